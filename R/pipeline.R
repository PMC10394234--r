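# End-to-end workflow: per-subject processing, cohort runs, and the study
# report reproducing the group-comparison / correlation / transition-model
# structure of the reference analysis.

#' Process one raw recording through the full sensor + source pipeline
#'
#' Average reference -> 1-20 Hz zero-phase filter -> 500 ms epochs with
#' 100 ms baseline -> artifact rejection (120 uV absolute, 60 uV EOG
#' peak-to-peak) -> 60% acceptance gate -> condition averages ->
#' deviant-minus-standard differences -> peak measures at the six analysis
#' electrodes and three-source activity estimates.
#'
#' @param raw An `mmn_raw` (FCz-referenced).
#' @param model An `mmn_source_model` built on the same montage.
#' @param config Optional parameter overrides, see [default_run_config()].
#' @return List: `gate`, `qc`, `surface` (peak measures data.frame),
#'   `sources` (source activity data.frame), `diffs` (difference waveforms),
#'   `included`.
#' @export
process_subject <- function(raw, model, config = default_run_config()) {
  p <- config$preprocess
  raw <- rereference_average(raw)
  raw <- bandpass(raw, p$low_hz, p$high_hz)
  ep <- segment(raw, pre_ms = p$baseline_ms, post_ms = p$epoch_post_ms)
  ep <- reject_artifacts(ep, p$amp_threshold_uv, p$eog_threshold_uv)
  gate <- subject_gate(ep, p$gate_ratio)
  qc <- qc_report(ep)
  if (!gate$include) {
    return(list(gate = gate, qc = qc, surface = NULL, sources = NULL,
                diffs = NULL, included = FALSE))
  }
  ev <- average_by_condition(ep)
  deviants <- setdiff(names(ev), "standard")
  diffs <- lapply(ev[deviants], compute_difference, standard = ev$standard)
  surf <- surface_measures(diffs, window_ms = config$peak_window_ms)
  src <- do.call(rbind, lapply(diffs, function(d) {
    sw <- estimate_source_waveforms(model, d)
    a <- source_activity(sw, window_ms = config$peak_window_ms,
                         reduction = config$source_reduction)
    cbind(condition = d$condition, a)
  }))
  rownames(src) <- NULL
  list(gate = gate, qc = qc, surface = surf, sources = src, diffs = diffs,
       included = TRUE)
}

#' Default pipeline configuration
#'
#' All paradigm and analysis constants surfaced as named fields with the
#' study defaults: 2,400 stimuli at 500 ms SOA, 1-20 Hz filter, 500 ms
#' epochs with 100 ms baseline, 120 uV amplitude and 60 uV EOG rejection
#' thresholds, 60% subject gate, 150-250 ms peak window.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    paradigm = list(n_standard = 1896L, n_deviant = 168L, soa_ms = 500L,
                    min_gap = 2L),
    head = list(shell_radii_m = c(0.071, 0.079, 0.085),
                conductivities_s_m = c(0.33, 0.0042, 0.33),
                series_truncation = 60L),
    source_coords_m = list(RS1 = c(-0.041, -0.026, 0.011),
                           RS2 = c(0.041, -0.026, 0.011),
                           RS3 = c(0.000, 0.025, 0.025)),
    preprocess = list(low_hz = 1, high_hz = 20, baseline_ms = 100,
                      epoch_post_ms = 400, amp_threshold_uv = 120,
                      eog_threshold_uv = 60, gate_ratio = 0.6),
    peak_window_ms = c(150, 250),
    source_reduction = "peak",
    design = list(group_sizes = c(50L, 74L, 74L, 13L),
                  transitions = c(0L, 3L, 10L, 2L),
                  noise_rms_uv = 2, blink_rate_hz = 0.1),
    master_seed = 1L
  )
}

#' Build a cohort design from a run configuration
#'
#' Applies the `design` block of a run configuration (group sizes,
#' transition counts, noise and blink settings) on top of
#' [default_study_design()].
#'
#' @param config A run configuration list.
#' @return An `mmn_design`.
#' @export
design_from_config <- function(config = default_run_config()) {
  d <- default_study_design(config$master_seed %||% 1L)
  dc <- config$design
  if (!is.null(dc)) {
    d$groups$n <- as.integer(dc$group_sizes %||% d$groups$n)
    d$groups$transitions <- as.integer(dc$transitions %||% d$groups$transitions)
    d$sim$noise_rms_uv <- dc$noise_rms_uv %||% d$sim$noise_rms_uv
    d$sim$blink_rate_hz <- dc$blink_rate_hz %||% d$sim$blink_rate_hz
    if (any(d$groups$transitions > d$groups$n)) {
      stop("design override: transition counts exceed group sizes")
    }
  }
  d
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys raise a validation error naming the key; missing keys fall
#' back to the defaults. The round-trip through YAML is lossless.
#'
#' @param path YAML file path.
#' @rdname run_config_io
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  check <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad)) {
      stop("unknown configuration key(s): ",
           paste0(prefix, bad, collapse = ", "))
    }
    for (nm in names(u)) {
      if (is.list(d[[nm]]) && !is.null(names(d[[nm]]))) {
        check(u[[nm]], d[[nm]], paste0(prefix, nm, "."))
      }
    }
  }
  check(user, defaults)
  merge_cfg <- function(d, u) {
    for (nm in names(u)) {
      d[[nm]] <- if (is.list(d[[nm]]) && !is.null(names(d[[nm]])) &&
                     is.list(u[[nm]])) merge_cfg(d[[nm]], u[[nm]])
        else u[[nm]]
    }
    d
  }
  merge_cfg(defaults, user)
}

#' @param config Configuration list.
#' @rdname run_config_io
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build the geometry/model bundle used by a run.
build_run_model <- function(config = default_run_config()) {
  montage <- build_montage()
  head <- head_model(config$head$shell_radii_m,
                     config$head$conductivities_s_m,
                     config$head$series_truncation)
  sources <- lapply(names(config$source_coords_m), function(nm) {
    regional_source(nm, config$source_coords_m[[nm]])
  })
  names(sources) <- names(config$source_coords_m)
  model <- build_source_model(montage, head, sources)
  list(montage = montage, head = head, sources = sources, model = model)
}

#' Run a complete synthetic study
#'
#' Simulates every subject of a cohort design, processes each recording
#' through the sensor and source pipeline (one subject in memory at a time),
#' and assembles the cohort table of measured MMN outcomes alongside the
#' generative profiles.
#'
#' @param design An `mmn_design` (default [default_study_design()]).
#' @param seed Master seed (default: the design's).
#' @param config Pipeline configuration.
#' @param progress Print one line per subject (default FALSE).
#' @return List of class `mmn_study`: `cohort` (one row per included
#'   subject: profile columns, gate ratio, per-electrode duration peak
#'   amplitudes `amp_<ch>`, per-source duration activities `src_<RSk>`, and
#'   `src_<RSk>_<condition>` for the other deviants), `excluded`
#'   (subject ids failing the gate), `report` (see [study_report()]),
#'   `seed`, `config`.
#' @export
run_study <- function(design = default_study_design(),
                      seed = design$master_seed,
                      config = default_run_config(),
                      progress = FALSE) {
  design$master_seed <- as.integer(seed)
  bundle <- build_run_model(config)
  seq <- generate_sequence(seed, config$paradigm$n_standard,
                           config$paradigm$n_deviant,
                           config$paradigm$soa_ms, config$paradigm$min_gap)
  profiles <- sample_profiles(design, seed)
  rows <- vector("list", nrow(profiles))
  excluded <- character()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    raw <- simulate_subject(prof, seq, bundle$montage, bundle$head,
                            sources = bundle$sources,
                            shape = design$sim$mmn_shape %||% "wavelet")
    res <- process_subject(raw, bundle$model, config)
    if (progress) {
      message(sprintf("[%d/%d] %s gate=%.2f %s", i, nrow(profiles),
                      prof$subject_id, res$gate$ratio,
                      if (res$included) "included" else "EXCLUDED"))
    }
    if (!res$included) {
      excluded <- c(excluded, prof$subject_id)
      next
    }
    surf <- res$surface[res$surface$condition == "duration", ]
    amp <- setNames(surf$amplitude_uv, paste0("amp_", surf$channel))
    src <- res$sources
    sd_ <- src[src$condition == "duration", ]
    sv <- setNames(sd_$activity_nam, paste0("src_", sd_$source))
    other <- src[src$condition != "duration", ]
    ov <- setNames(other$activity_nam,
                   paste0("src_", other$source, "_", other$condition))
    rows[[i]] <- cbind(prof,
                       data.frame(gate_ratio = res$gate$ratio),
                       as.data.frame(as.list(c(amp, sv, ov))))
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(cohort) <- NULL
  out <- list(cohort = cohort, excluded = excluded, seed = seed,
              config = config)
  out$report <- study_report(cohort)
  class(out) <- "mmn_study"
  out
}

#' @export
print.mmn_study <- function(x, ...) {
  cat("<mmn_study>", nrow(x$cohort), "included subjects,",
      length(x$excluded), "excluded; seed", x$seed, "\n")
  invisible(x)
}

#' Cohort report: group comparisons, correlations, transition models
#'
#' Reproduces the structure of the reference analysis from a cohort table:
#' mean +/- SD blocks per group for the six analysis electrodes and three
#' sources in the duration condition with controls-vs-at-risk and
#' across-subgroup one-way ANOVAs plus Bonferroni post-hoc annotations; the
#' correlation matrix of sex, age, duration-condition source activities and
#' GAF over the at-risk subjects; and unadjusted/adjusted logistic
#' transition models restricted to the UHR-criteria subjects (groups UHR and
#' UHR&BS) with inverse-coded, z-standardized source predictors.
#'
#' @param cohort Cohort table as produced by [run_study()].
#' @return List of class `mmn_report`: `group_table`, `correlations`,
#'   `transition_models`, `counts`.
#' @export
study_report <- function(cohort) {
  measures <- c(paste0("amp_", .analysis_electrodes),
                paste0("src_", c("RS1", "RS2", "RS3")))
  at_risk <- cohort$group != "CON"
  grp4 <- factor(cohort$group, levels = .groups)
  group_table <- do.call(rbind, lapply(measures, function(mv) {
    v <- cohort[[mv]]
    blocks <- vapply(c(list(CON = !at_risk, `at-risk` = at_risk),
                       setNames(lapply(.groups[-1], `==`, cohort$group),
                                .groups[-1])),
                     function(sel) {
                       sprintf("%.2f +/- %.2f", mean(v[sel]), sd(v[sel]))
                     }, character(1))
    a2 <- anova_oneway(v, ifelse(at_risk, "at-risk", "CON"), mv)
    a4 <- anova_oneway(v, grp4, mv)
    ph <- bonferroni_posthoc(v, grp4)
    sig <- ph[ph$p_adjusted < 0.05, , drop = FALSE]
    annot <- if (nrow(sig)) {
      paste(sprintf("%s %s %s (p=%.3g)", sig$group_a,
                    ifelse(sig$mean_diff > 0, ">", "<"), sig$group_b,
                    sig$p_adjusted), collapse = "; ")
    } else ""
    data.frame(measure = mv, t(blocks), p_con_vs_risk = a2$p,
               p_subgroups = a4$p, posthoc = annot, check.names = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(group_table) <- NULL
  cors <- correlation_matrix(
    data.frame(sex = cohort$sex[at_risk], age = cohort$age[at_risk],
               RS1_duration = cohort$src_RS1[at_risk],
               RS2_duration = cohort$src_RS2[at_risk],
               RS3_duration = cohort$src_RS3[at_risk],
               GAF = cohort$gaf[at_risk]))
  uhr <- cohort[cohort$group %in% c("UHR", "UHR&BS"), , drop = FALSE]
  trans <- list(note = "UHR-criteria subset too small for regression",
                unadjusted = NULL, adjusted = NULL)
  if (nrow(uhr) >= 10 && length(unique(uhr$transition)) == 2) {
    pred_cols <- c("sex", "age", "src_RS1", "src_RS2", "src_RS3", "gaf",
                   "sips_pos", "sips_neg")
    preds <- prepare_regression_predictors(
      uhr, pred_cols, invert = c("src_RS1", "src_RS2", "src_RS3"))
    names(preds) <- c("sex_male", "age", "RS1_duration_inv",
                      "RS2_duration_inv", "RS3_duration_inv", "gaf",
                      "sips_pos", "sips_neg")
    trans <- list(
      unadjusted = fit_logistic(uhr$transition, preds, "unadjusted",
                                on_separation = "report"),
      adjusted = fit_logistic(uhr$transition, preds, "adjusted",
                              on_separation = "report"))
  }
  structure(list(
    group_table = group_table,
    correlations = cors,
    transition_models = trans,
    counts = list(
      n_total = nrow(cohort),
      n_by_group = table(grp4),
      n_at_risk = sum(at_risk),
      n_transition = sum(cohort$transition),
      n_uhr_criteria = nrow(uhr),
      uhr_transition_split = c(no_transition = sum(!uhr$transition),
                               transition = sum(uhr$transition)))
  ), class = "mmn_report")
}

#' @export
print.mmn_report <- function(x, ...) {
  cat("== Group comparison (duration condition) ==\n")
  print(x$group_table, row.names = FALSE)
  cat("\n== Correlations (at-risk subjects, n =", x$correlations$n, ") ==\n")
  print(round(x$correlations$r, 3))
  cat("\n== Transition models (UHR-criteria subjects:",
      x$counts$uhr_transition_split[1], "vs",
      x$counts$uhr_transition_split[2], ") ==\n")
  if (!is.null(x$transition_models$unadjusted)) {
    print(x$transition_models$unadjusted, row.names = FALSE)
    print(x$transition_models$adjusted, row.names = FALSE)
  } else {
    cat(x$transition_models$note, "\n")
  }
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' TSV files for each table plus a single JSON summary at full precision.
#'
#' @param report An `mmn_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$group_table, file.path(dir, "group_table.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(report$correlations$r),
              file.path(dir, "correlations_r.tsv"), sep = "\t", quote = FALSE)
  tm <- report$transition_models
  if (!is.null(tm$unadjusted)) {
    write.table(rbind(tm$unadjusted, tm$adjusted),
                file.path(dir, "transition_models.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(counts = report$counts,
         group_table = report$group_table,
         correlations = list(r = report$correlations$r,
                             p = report$correlations$p,
                             n = report$correlations$n),
         transition_models = tm[!vapply(tm, is.null, logical(1))]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE, pretty = TRUE)
  invisible(dir)
}
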