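# Cohort statistics: group ANOVAs with Bonferroni post-hoc comparisons,
# correlation matrix, and unadjusted/adjusted logistic transition models
# with inverse coding and z-standardization.

#' One-way ANOVA of a measure across groups
#'
#' Classical between/within decomposition via [stats::aov()].
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param measure Optional measure name for the result.
#' @return List of class `mmn_anova`: `measure`, `F`, `df`, `p`.
#' @export
anova_oneway <- function(values, groups, measure = "measure") {
  groups <- factor(groups)
  tab <- table(groups[!is.na(values)])
  if (length(tab) < 2) stop("ANOVA requires at least two groups")
  if (any(tab < 2)) {
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  structure(list(measure = measure, F = s[1, "F value"],
                 df = c(s[1, "Df"], s[2, "Df"]), p = s[1, "Pr(>F)"]),
            class = "mmn_anova")
}

#' @export
print.mmn_anova <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n", x$measure,
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Bonferroni-adjusted pairwise post-hoc comparisons
#'
#' Two-sample pooled-variance t tests for every unordered pair of groups;
#' p values are multiplied by the number of pairs and capped at 1. Welch
#' tests are available via `pooled = FALSE`.
#'
#' @inheritParams anova_oneway
#' @param pooled Use pooled-variance t tests (default TRUE).
#' @return data.frame: group_a, group_b, mean_diff, direction, t, df, p_raw,
#'   p_adjusted.
#' @export
bonferroni_posthoc <- function(values, groups, pooled = TRUE) {
  groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2) stop("post-hoc comparisons require at least two groups")
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    if (length(a) < 2 || length(b) < 2) {
      stop("group(s) with fewer than 2 subjects: ",
           paste(pairs[, i], collapse = " or "))
    }
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- t.test(a, b, var.equal = pooled)
    }
    md <- mean(a) - mean(b)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               mean_diff = md, direction = sign(md),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  out$p_adjusted <- pmin(1, out$p_raw * m)
  out
}

#' Pearson correlation matrix with two-sided p values
#'
#' Binary columns (e.g. sex) may be passed as factors/characters with two
#' levels; they are encoded 0/1 so the Pearson r is the point-biserial
#' correlation. Zero-variance columns yield NA cells with a flag rather than
#' an error.
#'
#' @param data data.frame of the columns to correlate.
#' @return List of class `mmn_cormat`: `r`, `p`, `n`, `flagged` (logical
#'   matrix marking undefined cells).
#' @export
correlation_matrix <- function(data) {
  df <- as.data.frame(data)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) || is.factor(df[[j]])) {
      f <- factor(df[[j]])
      if (nlevels(f) > 2) stop("column '", names(df)[j],
                               "' has more than two levels")
      df[[j]] <- as.numeric(f) - 1
    }
  }
  cc <- complete.cases(df)
  if (sum(cc) < 3) stop("correlation matrix requires >= 3 complete observations")
  df <- df[cc, , drop = FALSE]
  k <- ncol(df)
  r <- matrix(NA_real_, k, k, dimnames = list(names(df), names(df)))
  p <- r
  flagged <- matrix(FALSE, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (sd(df[[i]]) == 0 || sd(df[[j]]) == 0) {
        flagged[i, j] <- TRUE
        next
      }
      ct <- cor.test(df[[i]], df[[j]])
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = nrow(df), flagged = flagged),
            class = "mmn_cormat")
}

#' @export
print.mmn_cormat <- function(x, digits = 3, ...) {
  cat("<mmn_cormat> n =", x$n, "\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Prepare predictors for the transition regressions
#'
#' Source-activity columns listed in `invert` are inverse coded (multiplied
#' by -1 so that larger values denote larger deficits), then every
#' continuous predictor is z-standardized to the mean and SD of the analysis
#' sample. Binary sex is recoded male = 1 / female = 0 and left
#' unstandardized.
#'
#' @param table data.frame of the analysis subset.
#' @param predictors Columns to transform/keep.
#' @param invert Subset of `predictors` to inverse code.
#' @return data.frame of transformed predictors.
#' @export
prepare_regression_predictors <- function(table,
                                          predictors,
                                          invert = character()) {
  out <- table[, predictors, drop = FALSE]
  for (nm in predictors) {
    v <- out[[nm]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      if (nlevels(f) != 2) stop("binary predictor '", nm,
                                "' must have exactly two levels")
      ref <- if ("male" %in% levels(f)) "male" else levels(f)[2]
      out[[nm]] <- as.numeric(f == ref)
      next
    }
    if (nm %in% invert) v <- -v
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      stop("cannot standardize zero-variance column '", nm, "'")
    }
    out[[nm]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  out
}

#' Logistic transition models
#'
#' Maximum-likelihood logistic regression with Wald 95% confidence
#' intervals. `mode = "unadjusted"` fits one single-predictor model per
#' column of `predictors`; `mode = "adjusted"` fits one joint model
#' containing all of them. Complete or quasi-complete separation is detected
#' (fitted probabilities at the 0/1 boundary or diverging coefficients) and
#' reported as non-convergence rather than returned as spurious estimates.
#'
#' @param outcome Logical or 0/1 vector (transition flags).
#' @param predictors data.frame of (already transformed) predictors.
#' @param mode `"unadjusted"` or `"adjusted"`.
#' @param on_separation `"error"` (default) raises a convergence error with
#'   a diagnostic; `"report"` returns the affected rows with NA estimates
#'   and `converged = FALSE`.
#' @return data.frame of class `mmn_logistic`: model, predictor, or, ci_lo,
#'   ci_hi, p, n_event, n_nonevent, converged.
#' @export
fit_logistic <- function(outcome, predictors,
                         mode = c("unadjusted", "adjusted"),
                         on_separation = c("error", "report")) {
  mode <- match.arg(mode)
  on_separation <- match.arg(on_separation)
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) {
    stop("outcome has a single class; logistic model undefined")
  }
  fit_one <- function(df, label) {
    dat <- cbind(data.frame(.y = y), df)
    warned <- FALSE
    fit <- withCallingHandlers(
      glm(.y ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    sep <- warned || !fit$converged || any(abs(coef(fit)[-1]) > 15)
    if (sep && on_separation == "error") {
      stop("logistic model '", label, "' did not converge (complete or ",
           "quasi-complete separation suspected; max |coef| = ",
           signif(max(abs(coef(fit)[-1])), 3), ")")
    }
    rows <- data.frame(
      model = label,
      predictor = rownames(co)[-1],
      or = exp(co[-1, 1]),
      ci_lo = exp(co[-1, 1] - 1.96 * co[-1, 2]),
      ci_hi = exp(co[-1, 1] + 1.96 * co[-1, 2]),
      p = co[-1, 4],
      n_event = sum(y == 1), n_nonevent = sum(y == 0),
      converged = !sep, stringsAsFactors = FALSE)
    if (sep) rows[, c("or", "ci_lo", "ci_hi", "p")] <- NA_real_
    rows
  }
  out <- if (mode == "unadjusted") {
    do.call(rbind, lapply(names(predictors), function(nm) {
      fit_one(predictors[, nm, drop = FALSE], paste0("unadjusted:", nm))
    }))
  } else {
    fit_one(predictors, "adjusted")
  }
  rownames(out) <- NULL
  class(out) <- c("mmn_logistic", "data.frame")
  out
}
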