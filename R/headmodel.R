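# Multi-shell spherical-head forward model.
#
# The scalp potential of a current dipole inside concentric conducting
# spherical shells is expanded in Legendre series. Per spherical harmonic
# degree n the radial dependence in shell j is A_j r^n + B_j r^-(n+1); the
# coefficients follow from potential and radial-current continuity at the
# interfaces and a no-current condition at the scalp surface. The per-degree
# surface gains g_n are solved numerically once per head model and cached.
# In the homogeneous limit g_n reduces to (2n+1)/n, the classic single-sphere
# solution, which serves as an analytic oracle in the test-suite.

#' Define a multi-shell spherical head model
#'
#' @param shell_radii_m Increasing radii (metres) of the shell boundaries,
#'   innermost (brain) to outermost (scalp). Default 71/79/85 mm.
#' @param conductivities_s_m Conductivity of each shell in S/m
#'   (brain/skull/scalp). Default 0.33/0.0042/0.33.
#' @param series_truncation Number of Legendre terms (>= 20, default 60).
#' @return An object of class `mmn_head`.
#' @export
head_model <- function(shell_radii_m = c(0.071, 0.079, 0.085),
                       conductivities_s_m = c(0.33, 0.0042, 0.33),
                       series_truncation = 60L) {
  stopifnot(length(shell_radii_m) == length(conductivities_s_m))
  if (any(diff(shell_radii_m) <= 0)) stop("shell radii must be strictly increasing")
  if (any(conductivities_s_m <= 0)) stop("conductivities must be positive")
  if (series_truncation < 20) stop("series_truncation must be >= 20")
  h <- structure(list(
    shell_radii_m = shell_radii_m,
    conductivities_s_m = conductivities_s_m,
    series_truncation = as.integer(series_truncation)
  ), class = "mmn_head")
  h$gains <- .shell_gains(h)
  h
}

#' @export
print.mmn_head <- function(x, ...) {
  cat("<mmn_head> radii", paste(x$shell_radii_m * 1000, collapse = "/"),
      "mm, conductivities", paste(x$conductivities_s_m, collapse = "/"),
      "S/m,", x$series_truncation, "series terms\n")
  invisible(x)
}

# Per-degree surface gains g_n (n = 1..N) for unit primary coefficient.
# Radii are non-dimensionalized by the scalp radius. For L shells, the
# unknowns are A_1 and (A_j, B_j) for j = 2..L; B_1 = 1 is the source term.
# To keep the linear system well conditioned at high degree, the unknowns
# are rescaled per shell: the A coefficient of shell j is expressed at its
# outer radius and the B coefficient at its inner radius, so all matrix
# entries stay O(n).
.shell_gains <- function(head) {
  L <- length(head$shell_radii_m)
  c_r <- head$shell_radii_m / head$shell_radii_m[L]
  sig <- head$conductivities_s_m
  N <- head$series_truncation
  g <- numeric(N)
  idxA <- function(j) if (j == 1L) 1L else 2L * j - 2L
  idxB <- function(j) 2L * j - 1L           # defined for j >= 2
  for (n in seq_len(N)) {
    nun <- 2L * L - 1L                      # A1, A2, B2, ..., AL, BL (scaled)
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    row <- 0L
    src <- c_r[1]^-(n + 1)                  # source term B1 = 1 at c_1
    for (j in seq_len(L - 1L)) {            # interface j between shell j, j+1
      r <- c_r[j]
      rin_j <- if (j >= 2L) c_r[j - 1L] else NA_real_
      # potential continuity (A_j at outer radius r: coefficient 1)
      row <- row + 1L
      M[row, idxA(j)] <- 1
      if (j > 1L) M[row, idxB(j)] <- (rin_j / r)^(n + 1)
      M[row, idxA(j + 1L)] <- -(r / c_r[j + 1L])^n
      M[row, idxB(j + 1L)] <- -1
      if (j == 1L) rhs[row] <- -src
      # radial current continuity, multiplied through by r
      row <- row + 1L
      M[row, idxA(j)] <- sig[j] * n
      if (j > 1L) M[row, idxB(j)] <- -sig[j] * (n + 1) * (rin_j / r)^(n + 1)
      M[row, idxA(j + 1L)] <- -sig[j + 1L] * n * (r / c_r[j + 1L])^n
      M[row, idxB(j + 1L)] <- sig[j + 1L] * (n + 1)
      if (j == 1L) rhs[row] <- sig[1L] * (n + 1) * src
    }
    # outer surface: no radial current at r = 1
    row <- row + 1L
    M[row, idxA(L)] <- n
    if (L == 1L) rhs[row] <- (n + 1)        # B1 = 1 is the source term
    else M[row, idxB(L)] <- -(n + 1) * c_r[L - 1L]^(n + 1)
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stop("forward-model series did not solve at degree ", n,
           " (ill-conditioned shell system): ", conditionMessage(e))
    })
    g[n] <- if (L == 1L) sol[idxA(1L)] + 1
      else sol[idxA(L)] + sol[idxB(L)] * c_r[L - 1L]^(n + 1)
    if (!is.finite(g[n])) {
      stop("forward-model series non-finite at degree ", n,
           "; reduce series_truncation or check conductivities")
    }
  }
  g
}

# Legendre P_n(x) and associated P_n^1(x) = sqrt(1-x^2) P_n'(x) for
# n = 1..N, by upward recurrence. x may be a vector; returns list of
# N x length(x) matrices.
.legendre_terms <- function(x, N) {
  nx <- length(x)
  P <- matrix(0, N, nx)
  dP <- matrix(0, N, nx)           # derivative P_n'(x)
  pm1 <- rep(1, nx); p <- x        # P_0, P_1
  dm1 <- rep(0, nx); d <- rep(1, nx)
  P[1, ] <- p; dP[1, ] <- d
  if (N > 1) {
    for (n in 2:N) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      dn <- dm1 + (2 * n - 1) * p
      pm1 <- p; p <- pn
      dm1 <- d; d <- dn
      P[n, ] <- pn; dP[n, ] <- dn
    }
  }
  s <- sqrt(pmax(0, 1 - x^2))
  list(P = P, P1 = sweep(dP, 2, s, `*`))
}

# Raw (unreferenced) potential of a dipole at `location` (m) with moment
# `moment` (nAm) at surface points given by unit directions `dirs` (k x 3).
# Returns microvolts.
.dipole_potential_raw <- function(head, location, moment, dirs) {
  R <- head$shell_radii_m[length(head$shell_radii_m)]
  b <- sqrt(sum(location^2))
  if (b >= head$shell_radii_m[1]) {
    stop("dipole lies outside the brain shell (|location| = ",
         signif(b, 4), " m >= ", head$shell_radii_m[1], " m)")
  }
  N <- head$series_truncation
  if (all(moment == 0)) return(numeric(nrow(dirs)))
  if (b < 1e-12) {
    # central dipole: only n = 1 survives, any axis works
    bhat <- c(0, 0, 1)
  } else {
    bhat <- location / b
  }
  x <- as.numeric(dirs %*% bhat)           # cos(gamma) per electrode
  x <- pmin(1, pmax(-1, x))
  leg <- .legendre_terms(x, N)
  tvec <- dirs - outer(x, bhat)            # tangential direction (in-plane)
  tn <- sqrt(rowSums(tvec^2))
  safe <- tn > 1e-12
  tvec[safe, ] <- tvec[safe, , drop = FALSE] / tn[safe]
  tvec[!safe, ] <- 0
  q_r <- sum(moment * bhat)
  q_t <- as.numeric(tvec %*% moment)
  bp <- (b / R)^(seq_len(N) - 1)           # b'^(n-1)
  n_seq <- seq_len(N)
  wr <- head$gains * n_seq * bp            # weights for radial part
  wt <- head$gains * bp                    # weights for tangential part
  # V = k * sum_n [ wr_n q_r P_n + wt_n q_t P_n^1 ]
  vr <- as.numeric(crossprod(leg$P, wr))
  vt <- as.numeric(crossprod(leg$P1, wt))
  k <- 1 / (4 * pi * head$conductivities_s_m[1] * R^2)
  (q_r * vr + q_t * vt) * k * 1e-3         # nAm -> uV
}

#' Scalp potential of a single dipole
#'
#' Computes the average-referenced potential (microvolts) of a dipole inside
#' the brain shell at every montage channel. The average reference is taken
#' over the scalp EEG channels; the EOG channel carries its own forward
#' potential re-expressed against that reference.
#'
#' @param head An `mmn_head`.
#' @param location Dipole location, metres, head frame (strictly inside the
#'   brain shell).
#' @param moment Dipole moment, nAm (3-vector).
#' @param montage An `mmn_montage`.
#' @param reference `"average"` (default), `"none"` (raw model potential) or
#'   `"FCz"` (recording reference).
#' @return Named numeric vector, one value per channel, in microvolts.
#' @export
dipole_potential <- function(head, location, moment, montage,
                             reference = c("average", "none", "FCz")) {
  reference <- match.arg(reference)
  dirs <- montage$positions / montage$scalp_radius_m
  v <- .dipole_potential_raw(head, location, moment, dirs)
  if (reference == "average") {
    v <- v - mean(v[eeg_channels(montage)])
  } else if (reference == "FCz") {
    vref <- .dipole_potential_raw(head, location, moment,
                                  rbind(montage$reference_position /
                                          montage$scalp_radius_m))
    v <- v - vref
  }
  names(v) <- montage$channel_names
  v
}

#' Define a regional source
#'
#' A regional source is a brain location carrying three orthogonal unit
#' dipoles, capturing local activity of any orientation.
#'
#' @param label Source label (e.g. `"RS1"`).
#' @param location_m Location in metres, head frame.
#' @param orientations 3 x 3 matrix whose rows are orthonormal orientation
#'   vectors; defaults to the identity basis.
#' @export
regional_source <- function(label, location_m, orientations = diag(3)) {
  stopifnot(is.matrix(orientations), all(dim(orientations) == c(3, 3)))
  if (max(abs(orientations %*% t(orientations) - diag(3))) > 1e-10) {
    stop("orientations of source '", label, "' are not orthonormal")
  }
  structure(list(label = label, location_m = location_m,
                 orientations = orientations), class = "mmn_source")
}

#' Default three-source MMN model geometry
#'
#' Bilateral auditory-cortex sources on the transverse temporal gyri
#' (Brodmann area 41) and a frontal source in the anterior cingulate
#' (Brodmann area 24), at canonical atlas centroids expressed in metres in
#' the head frame (origin at the sphere centre).
#'
#' @return List of three `mmn_source` objects named RS1 (left temporal),
#'   RS2 (right temporal), RS3 (frontal).
#' @export
default_sources <- function() {
  list(
    RS1 = regional_source("RS1", c(-0.041, -0.026, 0.011)),
    RS2 = regional_source("RS2", c(0.041, -0.026, 0.011)),
    RS3 = regional_source("RS3", c(0.000, 0.025, 0.025))
  )
}

#' Lead field of a regional source
#'
#' Column k is the average-referenced scalp pattern of a unit (1 nAm) dipole
#' along the source's k-th orientation.
#'
#' @inheritParams dipole_potential
#' @param source An `mmn_source`.
#' @return channels x 3 gain matrix (microvolts per nAm).
#' @export
regional_leadfield <- function(head, source, montage,
                               reference = "average") {
  g <- vapply(1:3, function(k) {
    dipole_potential(head, source$location_m, source$orientations[k, ],
                     montage, reference = reference)
  }, numeric(length(montage$channel_names)))
  colnames(g) <- paste(source$label, 1:3, sep = "_o")
  g
}

#' Assemble the lead field of several regional sources
#'
#' @inheritParams regional_leadfield
#' @param sources List of `mmn_source` objects.
#' @return An `mmn_leadfield`: list with `gains` (channels x 3k matrix,
#'   microvolts per nAm, average-referenced over EEG channels),
#'   `channel_order`, `source_order`, and `condition_number` of the gain
#'   matrix restricted to EEG channels.
#' @export
assemble_leadfield <- function(head, sources, montage) {
  if (length(sources) < 1) stop("at least one source is required")
  blocks <- lapply(sources, regional_leadfield, head = head, montage = montage)
  gains <- do.call(cbind, blocks)
  eeg <- eeg_channels(montage)
  sv <- svd(gains[eeg, , drop = FALSE])$d
  if (min(sv) < max(sv) * 1e-10) {
    stop("assembled lead field is rank deficient for sources: ",
         paste(vapply(sources, `[[`, "", "label"), collapse = ", "))
  }
  structure(list(
    gains = gains,
    channel_order = montage$channel_names,
    source_order = vapply(sources, `[[`, "", "label"),
    condition_number = max(sv) / min(sv)
  ), class = "mmn_leadfield")
}

#' @export
print.mmn_leadfield <- function(x, ...) {
  cat("<mmn_leadfield>", nrow(x$gains), "channels x", ncol(x$gains),
      "source orientations; condition number",
      signif(x$condition_number, 4), "\n")
  invisible(x)
}
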