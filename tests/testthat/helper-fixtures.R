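# Shared fixtures, built once per test run.

fx <- new.env()

fx_montage <- function() {
  if (is.null(fx$montage)) fx$montage <- build_montage()
  fx$montage
}

fx_head <- function() {
  if (is.null(fx$head)) fx$head <- head_model()
  fx$head
}

fx_model <- function() {
  if (is.null(fx$model)) fx$model <- build_source_model(fx_montage(), fx_head())
  fx$model
}

# A small oddball sequence for unit tests (fast to simulate/process).
fx_small_sequence <- function(seed = 3, n_standard = 48L, n_deviant = 4L) {
  generate_sequence(seed, n_standard = n_standard, n_deviant = n_deviant)
}

# One control-group profile with overridable noise/blink settings.
fx_profile <- function(noise_rms = 0, blink_rate = 0, seed = 5, row = 1) {
  p <- sample_profiles(default_study_design(), seed)[row, ]
  p$noise_rms_uv <- noise_rms
  p$blink_rate_hz <- blink_rate
  p
}

# Closed-form surface potential of a dipole in a homogeneous conducting
# sphere (insulated outside); independent oracle for the multi-shell series.
closed_form_sphere_potential <- function(location, moment, montage, sigma) {
  R <- montage$scalp_radius_m
  dirs <- montage$positions / R
  b <- sqrt(sum(location^2))
  bhat <- location / b
  vapply(seq_len(nrow(dirs)), function(i) {
    r <- dirs[i, ] * R
    d <- r - location
    dn <- sqrt(sum(d^2))
    x <- sum(dirs[i, ] * bhat)
    tt <- b / R
    s <- dn / R
    that <- dirs[i, ] - x * bhat
    tn <- sqrt(sum(that^2))
    that <- if (tn > 1e-12) that / tn else c(0, 0, 0)
    qr <- sum(moment * bhat)
    qt <- sum(moment * that)
    sinth <- sqrt(max(0, 1 - x^2))
    v <- 2 * sum(moment * d) / dn^3 +
      (qr / (b * R)) * (1 / s - 1) +
      (qt / (b * R)) * sinth * tt * (s + 1) / (s * (1 - tt * x + s))
    v / (4 * pi * sigma) * 1e-3            # nAm -> microvolts
  }, numeric(1))
}

# Build an epochs object directly from a trials array (for rejection /
# averaging unit tests without simulating a recording).
fx_epochs <- function(trials, condition, montage = fx_montage(),
                      fs_hz = 500) {
  nsamp <- dim(trials)[1]
  npre <- 50L
  structure(list(
    trials = trials,
    time_ms = (seq_len(nsamp) - npre - 1L) * 1000 / fs_hz,
    condition = condition,
    accepted = rep(TRUE, dim(trials)[2]),
    rejection_reason = rep("none", dim(trials)[2]),
    montage = montage, fs_hz = fs_hz
  ), class = "mmn_epochs")
}
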