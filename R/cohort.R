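# Synthetic cohort generation: subject profiles with group-specific frontal
# MMN deficits, and raw-EEG simulation (event-locked source activity
# projected through the head model, coloured background noise, blinks).

.groups <- c("CON", "BS", "UHR&BS", "UHR")

#' Default cohort design
#'
#' Instantiates the study conditions of the reference cohort: 50 healthy
#' controls and 161 at-risk subjects (74 basic-symptoms-only, 74 combined
#' UHR&BS, 13 UHR-only) with 15 transitions to manifest schizophrenia
#' (3/10/2 per at-risk group). Duration-condition source-amplitude moments
#' (nAm, mean and SD per group and regional source) and demographic/clinical
#' covariate moments are the reference cohort group statistics; subjects in
#' UHR-criteria groups draw their source amplitudes from the
#' transition-stratified moments.
#'
#' @param master_seed Master seed for cohort sampling (default 1).
#' @return An object of class `mmn_design`.
#' @export
default_study_design <- function(master_seed = 1L) {
  sm <- function(...) {
    m <- matrix(c(...), nrow = 4, byrow = TRUE,
                dimnames = list(.groups, c("mean", "sd")))
    m
  }
  design <- list(
    groups = data.frame(
      group = .groups,
      n = c(50L, 74L, 74L, 13L),
      transitions = c(0L, 3L, 10L, 2L),
      stringsAsFactors = FALSE
    ),
    # duration-condition amplitude moments per group (nAm)
    source_moments = list(
      RS1 = sm(14.71, 8.51, 14.86, 7.48, 16.96, 7.13, 18.33, 8.47),
      RS2 = sm(13.08, 5.54, 13.66, 6.38, 15.74, 7.79, 14.56, 9.51),
      RS3 = sm(13.95, 7.17, 7.72, 4.16, 8.80, 4.42, 9.23, 5.65)
    ),
    # transition-stratified moments (UHR-criteria subjects; sign restored
    # from the inverse coding of the reference regression table)
    transition_moments = list(
      no_transition = c(RS1 = 16.62, RS2 = 14.38, RS3 = 8.29),
      no_transition_sd = c(RS1 = 7.55, RS2 = 7.87, RS3 = 4.68),
      transition = c(RS1 = 13.34, RS2 = 15.66, RS3 = 5.21),
      transition_sd = c(RS1 = 4.92, RS2 = 9.20, RS3 = 2.89)
    ),
    covariates = list(
      age = sm(21.00, 5.55, 23.11, 5.69, 18.91, 4.86, 17.15, 3.98),
      male_p = c(CON = 0.540, BS = 0.6216, `UHR&BS` = 0.5541, UHR = 0.7692),
      sips_pos = sm(NA, NA, 4.58, 3.29, 10.86, 3.68, 10.44, 2.68),
      sips_neg = sm(NA, NA, 10.46, 5.95, 13.32, 6.01, 12.46, 6.36),
      gaf = sm(NA, NA, 58.92, 14.75, 52.01, 12.19, 57.67, 10.51)
    ),
    sim = list(
      noise_rms_uv = 2,        # single-trial RMS after 1-20 Hz filtering
                               # (calibrated to averaged-domain SNR; see vignette)
      blink_rate_hz = 0.1,
      blink_amp_uv = 80,
      standard_amp_nam = 20,
      latency_mean_ms = 200,
      latency_sd_ms = 20,
      amp_floor_nam = 0.5,
      mmn_shape = "wavelet",   # "wavelet" (zero-mean) or "bump" (unipolar)
      noise_rank = 16L
    ),
    master_seed = as.integer(master_seed)
  )
  structure(design, class = "mmn_design")
}

#' @export
print.mmn_design <- function(x, ...) {
  cat("<mmn_design>", sum(x$groups$n), "subjects (",
      paste(sprintf("%s=%d", x$groups$group, x$groups$n), collapse = ", "),
      "),", sum(x$groups$transitions), "transitions\n")
  invisible(x)
}

# Truncated-normal draw with a positive floor, location-corrected so the
# post-truncation expectation equals `mean` (the design moments are the
# group means the cohort should reproduce). sd = 0 gives the mean exactly
# (degenerate draw).
.rtnorm_floor <- function(n, mean, sd, floor) {
  if (!is.finite(mean) || is.na(sd)) return(rep(NA_real_, n))
  if (sd == 0) {
    if (mean < floor) stop("degenerate amplitude draw below the positive floor")
    return(rep(mean, n))
  }
  if (mean <= floor + 0.05 * sd) {
    stop("infeasible truncation: target mean ", mean,
         " is too close to (or below) the floor ", floor)
  }
  tmean <- function(mu) {
    a <- (floor - mu) / sd
    # inverse Mills ratio, asymptotic form for deep truncation
    h <- if (a > 8) a + 1 / a else dnorm(a) / (1 - pnorm(a))
    mu + sd * h
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       c(mean - 40 * sd, mean), tol = 1e-10)$root
  x <- rnorm(n, mu, sd)
  while (any(bad <- x < floor)) x[bad] <- rnorm(sum(bad), mu, sd)
  x
}

#' Sample subject profiles from a cohort design
#'
#' Amplitudes are truncated-normal draws (floor
#' `design$sim$amp_floor_nam` nAm) at the design moments: UHR-criteria
#' subjects (groups UHR and UHR&BS) draw all three duration-condition source
#' amplitudes from the transition-stratified moments; basic-symptoms-only
#' transition subjects draw the frontal (RS3) amplitude from the transition
#' moments and the temporal amplitudes from their group moments; everyone
#' else draws from group moments. Frequency- and intensity-condition
#' amplitudes are drawn at control-group moments for all groups (these
#' conditions showed no group structure). MMN peak latencies are
#' truncated-normal within 150-250 ms, snapped to the 2 ms sample grid.
#'
#' @param design An `mmn_design`.
#' @param seed Seed (default the design's master seed).
#' @return data.frame of class `mmn_profiles`, one row per subject.
#' @export
sample_profiles <- function(design, seed = design$master_seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(design$groups)), function(gi) {
      g <- design$groups$group[gi]
      n <- design$groups$n[gi]
      if (n == 0) return(NULL)
      ntr <- design$groups$transitions[gi]
      if (ntr > n) stop("design error: transitions exceed group size for ", g)
      transition <- rep(FALSE, n)
      transition[sample.int(n, ntr)] <- TRUE
      floor <- design$sim$amp_floor_nam
      tm <- design$transition_moments
      uhr_criteria <- g %in% c("UHR", "UHR&BS")
      amp <- sapply(c("RS1", "RS2", "RS3"), function(srcname) {
        mom <- design$source_moments[[srcname]][g, ]
        a <- .rtnorm_floor(n, mom["mean"], mom["sd"], floor)
        if (uhr_criteria) {
          a[!transition] <- .rtnorm_floor(sum(!transition),
                                          tm$no_transition[srcname],
                                          tm$no_transition_sd[srcname], floor)
          a[transition] <- .rtnorm_floor(sum(transition),
                                         tm$transition[srcname],
                                         tm$transition_sd[srcname], floor)
        } else if (srcname == "RS3" && any(transition)) {
          a[transition] <- .rtnorm_floor(sum(transition),
                                         tm$transition[srcname],
                                         tm$transition_sd[srcname], floor)
        }
        a
      })
      amp <- matrix(amp, nrow = n,
                    dimnames = list(NULL, c("RS1", "RS2", "RS3")))
      con_amp <- sapply(c("RS1", "RS2", "RS3"), function(srcname) {
        mom <- design$source_moments[[srcname]]["CON", ]
        cbind(.rtnorm_floor(n, mom["mean"], mom["sd"], floor),
              .rtnorm_floor(n, mom["mean"], mom["sd"], floor))
      })
      con_amp <- matrix(con_amp, nrow = 2L * n,
                        dimnames = list(NULL, c("RS1", "RS2", "RS3")))
      lat <- .rtnorm_floor(n, design$sim$latency_mean_ms,
                           design$sim$latency_sd_ms, 150)
      lat <- pmin(250, lat)
      lat <- round(lat / 2) * 2            # snap to the 500 Hz sample grid
      cov <- design$covariates
      data.frame(
        subject_id = sprintf("%s_%03d", gsub("&", "", g), seq_len(n)),
        group = g, transition = transition,
        rs1_amp = amp[, "RS1"], rs2_amp = amp[, "RS2"], rs3_amp = amp[, "RS3"],
        rs1_amp_frequency = con_amp[seq_len(n), "RS1"],
        rs2_amp_frequency = con_amp[seq_len(n), "RS2"],
        rs3_amp_frequency = con_amp[seq_len(n), "RS3"],
        rs1_amp_intensity = con_amp[n + seq_len(n), "RS1"],
        rs2_amp_intensity = con_amp[n + seq_len(n), "RS2"],
        rs3_amp_intensity = con_amp[n + seq_len(n), "RS3"],
        mmn_peak_latency_ms = lat,
        standard_response_amp = design$sim$standard_amp_nam,
        noise_rms_uv = design$sim$noise_rms_uv,
        blink_rate_hz = design$sim$blink_rate_hz,
        age = rnorm(n, cov$age[g, "mean"], cov$age[g, "sd"]),
        sex = ifelse(runif(n) < cov$male_p[[g]], "male", "female"),
        sips_pos = if (is.na(cov$sips_pos[g, "mean"])) rep(NA_real_, n) else
          rnorm(n, cov$sips_pos[g, "mean"], cov$sips_pos[g, "sd"]),
        sips_neg = if (is.na(cov$sips_neg[g, "mean"])) rep(NA_real_, n) else
          rnorm(n, cov$sips_neg[g, "mean"], cov$sips_neg[g, "sd"]),
        gaf = if (is.na(cov$gaf[g, "mean"])) rep(NA_real_, n) else
          rnorm(n, cov$gaf[g, "mean"], cov$gaf[g, "sd"]),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    out$subject_seed <- derive_seeds(seed, nrow(out))
    rownames(out) <- NULL
    class(out) <- c("mmn_profiles", "data.frame")
    out
  })
}

# ---- source response templates ------------------------------------------

# Zero-mean MMN transient: raised-cosine envelope (300 ms full width) times
# a 7 Hz cosine carrier, unit peak at the centre. Band-limited to the
# analysis band so the zero-phase 1-20 Hz filter preserves its peak.
.mmn_wavelet <- function(t_ms, latency_ms, env_width_ms = 300, carrier_hz = 7) {
  dt <- (t_ms - latency_ms) / 1000
  env <- ifelse(abs(dt) <= env_width_ms / 2000,
                0.5 * (1 + cos(2 * pi * dt * 1000 / env_width_ms)), 0)
  env * cos(2 * pi * carrier_hz * dt)
}

# Unipolar raised-cosine bump (100 ms full width), unit peak.
.mmn_bump <- function(t_ms, latency_ms, width_ms = 100) {
  dt <- t_ms - latency_ms
  ifelse(abs(dt) <= width_ms / 2,
         0.5 * (1 + cos(2 * pi * dt / width_ms)), 0)
}

# Obligatory auditory response to any tone at the temporal sources:
# biphasic transient centred at 100 ms.
.standard_shape <- function(t_ms, centre_ms = 100, width_ms = 150) {
  dt <- t_ms - centre_ms
  env <- ifelse(abs(dt) <= width_ms / 2,
                0.5 * (1 + cos(2 * pi * dt / width_ms)), 0)
  env * sin(2 * pi * dt / width_ms)
}

#' Source activity templates for one stimulus kind
#'
#' Standards evoke only the obligatory biphasic auditory response at the two
#' temporal sources. Deviants additionally evoke the MMN component at all
#' three sources, with per-source deviant-minus-standard peak magnitude equal
#' to the profile's amplitude for that condition, peaking at the profile's
#' latency.
#'
#' @param profile One row of an `mmn_profiles` data.frame.
#' @param kind One of `"standard"`, `"duration"`, `"frequency"`,
#'   `"intensity"`.
#' @param fs_hz Sampling rate (default 500).
#' @param shape MMN component shape: `"wavelet"` (zero-mean, default) or
#'   `"bump"` (unipolar raised cosine).
#' @return matrix (samples x 3 sources, nAm) covering 0-400 ms post-onset.
#' @export
source_response_templates <- function(profile, kind, fs_hz = 500,
                                      shape = c("wavelet", "bump")) {
  shape <- match.arg(shape)
  t_ms <- (seq_len(0.4 * fs_hz) - 1) * 1000 / fs_hz
  out <- matrix(0, length(t_ms), 3,
                dimnames = list(NULL, c("RS1", "RS2", "RS3")))
  std <- profile$standard_response_amp * .standard_shape(t_ms)
  out[, "RS1"] <- std
  out[, "RS2"] <- std
  if (kind != "standard") {
    suffix <- if (kind == "duration") "" else paste0("_", kind)
    w <- if (shape == "wavelet") {
      .mmn_wavelet(t_ms, profile$mmn_peak_latency_ms)
    } else {
      .mmn_bump(t_ms, profile$mmn_peak_latency_ms)
    }
    for (srcname in c("RS1", "RS2", "RS3")) {
      ampcol <- paste0(tolower(srcname), "_amp", suffix)
      out[, srcname] <- out[, srcname] + profile[[ampcol]] * w
    }
  }
  out
}

# Effective MMN source orientations: unit vectors chosen per source so that
# the average-referenced projection is maximally negative at Fz, producing
# the fronto-central MMN negativity.
mmn_orientations <- function(leadfield, montage) {
  fz <- match("Fz", montage$channel_names)
  ori <- matrix(0, 3, length(leadfield$source_order),
                dimnames = list(NULL, leadfield$source_order))
  for (k in seq_along(leadfield$source_order)) {
    gfz <- leadfield$gains[fz, 3 * (k - 1) + 1:3]
    ori[, k] <- -gfz / sqrt(sum(gfz^2))
  }
  ori
}

# ---- raw EEG simulation --------------------------------------------------

# Spatially-correlated band-limited background noise. `nfft` >= n. Returns
# n x nch matrix whose expected RMS after the 1-20 Hz analysis band-pass
# equals rms_uv on every channel.
.simulate_noise <- function(n, nch, fs_hz, rms_uv, montage, rank = 16L) {
  if (rms_uv == 0) return(matrix(0, n, nch))
  nfft <- nextn(n, c(2, 3, 5))
  f <- fft_freqs(nfft, fs_hz)
  af <- abs(f)
  band <- which(af >= 1 & af <= 45)
  a <- 1 / sqrt(af[band])                        # 1/f power tilt in 1-45 Hz
  Hb <- bandpass_response(f[band])
  # scale so that Var(x after the analysis band-pass) = rms^2 (per
  # unit-norm mixing row); ifft carries a 1/nfft factor per draw
  a <- a * rms_uv * nfft / sqrt(sum(a^2 * Hb^2))
  npair <- as.integer(ceiling(rank / 2))
  Zb <- matrix(complex(real = rnorm(length(band) * npair),
                       imaginary = rnorm(length(band) * npair)),
               length(band), npair) * a
  basis <- cpp_spectrum_to_noise(Zb, band, nfft, n)[, seq_len(rank),
                                                    drop = FALSE]
  # smooth random mixing: angular-distance kernel times Gaussian weights
  dirs <- montage$positions / montage$scalp_radius_m
  cosang <- tcrossprod(dirs)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  Ks <- exp(-(acos(cosang) / 1.0)^2)
  M <- Ks %*% matrix(rnorm(nch * rank), nch, rank)
  M <- M / sqrt(rowSums(M^2))
  basis %*% t(M)
}

# Stereotyped blink transient: 400 ms raised-cosine, frontal-dominant scalp
# pattern with the mirrored (negative) deflection on the infra-orbital EOG
# channel.
.blink_template <- function(montage, fs_hz, amp_uv = 80) {
  nb <- as.integer(0.4 * fs_hz)
  t <- (seq_len(nb) - 1) / fs_hz
  wave <- 0.5 * (1 - cos(2 * pi * t / 0.4))
  dirs <- montage$positions / montage$scalp_radius_m
  eye <- dirs[match(montage$eog_channel, montage$channel_names), ]
  ang <- acos(pmin(1, pmax(-1, as.numeric(dirs %*% eye))))
  w <- exp(-2.0 * ang)
  w[match(montage$eog_channel, montage$channel_names)] <- -1
  amp_uv * outer(wave, w)
}

#' Simulate one subject's raw EEG recording
#'
#' The recording is the sum of (a) lead-field-projected source responses at
#' every stimulus onset, (b) spatially-correlated 1-45 Hz background noise
#' with 1/f spectral tilt, calibrated so its RMS after the 1-20 Hz analysis
#' filter equals the profile's `noise_rms_uv`, and (c) stereotyped blink
#' transients arriving as a Poisson process at `blink_rate_hz`, mirrored on
#' the EOG channel. Data are expressed against the FCz recording reference.
#' Deterministic for a given seed.
#'
#' @param profile One row of an `mmn_profiles` data.frame.
#' @param seq An `mmn_sequence`.
#' @param montage An `mmn_montage`.
#' @param head An `mmn_head`.
#' @param seed Seed; defaults to the profile's `subject_seed`.
#' @param sources Regional sources (default [default_sources()]).
#' @param shape MMN shape override (default from the profile if present).
#' @return An `mmn_raw` referenced to FCz.
#' @export
simulate_subject <- function(profile, seq, montage, head,
                             seed = profile$subject_seed,
                             sources = default_sources(),
                             shape = "wavelet") {
  fs <- 500
  lf_rec <- assemble_leadfield_cached(head, sources, montage, reference = "FCz")
  lf_avg <- assemble_leadfield_cached(head, sources, montage, reference = "average")
  ori <- mmn_orientations(lf_avg, montage)
  # per-source recording-reference projection patterns (32 x 3)
  proj <- sapply(seq_along(sources), function(k) {
    lf_rec$gains[, 3 * (k - 1) + 1:3] %*% ori[, k]
  })
  nch <- length(montage$channel_names)
  pre_roll <- as.integer(fs)                     # 1 s before the first onset
  last_on <- max(seq$events$onset_ms)
  n <- pre_roll + as.integer(round(last_on / 1000 * fs)) + as.integer(0.4 * fs) +
    as.integer(fs %/% 2)
  with_seed(seed, {
    data <- .simulate_noise(n, nch, fs, profile$noise_rms_uv, montage,
                            rank = 16L)
    # event-locked activity, one template per stimulus kind
    onsets <- pre_roll + as.integer(round(seq$events$onset_ms / 1000 * fs)) + 1L
    for (kind in unique(seq$events$kind)) {
      s_tc <- source_response_templates(profile, kind, fs, shape = shape)
      tpl <- s_tc %*% t(proj)                    # samples x channels
      sel <- seq$events$kind == kind
      cpp_add_events(data, tpl, onsets[sel], rep(1, sum(sel)))
    }
    # blinks
    if (profile$blink_rate_hz > 0) {
      nb <- rpois(1, profile$blink_rate_hz * n / fs)
      if (nb > 0) {
        bt <- .blink_template(montage, fs)
        bon <- sort(sample.int(n - nrow(bt), nb))
        cpp_add_events(data, bt, bon, rep(1, nb))
      }
    }
    colnames(data) <- montage$channel_names
    raw_recording(data, montage, seq$events, fs_hz = fs,
                  first_onset_sample = pre_roll + 1L, reference = "FCz",
                  subject_id = profile$subject_id)
  })
}

# Lead-field cache keyed by head/source/montage geometry, so cohort
# simulation does not recompute the forward model per subject.
.lf_cache <- new.env(parent = emptyenv())

assemble_leadfield_cached <- function(head, sources, montage,
                                      reference = "average") {
  key <- paste(reference,
               paste(signif(unlist(c(head$shell_radii_m, head$conductivities_s_m,
                                     lapply(sources, `[[`, "location_m"))), 10),
                     collapse = ","),
               paste(montage$channel_names, collapse = ","),
               signif(montage$scalp_radius_m, 10), sep = "|")
  if (!is.null(.lf_cache[[key]])) return(.lf_cache[[key]])
  if (reference == "average") {
    lf <- assemble_leadfield(head, sources, montage)
  } else {
    blocks <- lapply(sources, regional_leadfield, head = head,
                     montage = montage, reference = reference)
    gains <- do.call(cbind, blocks)
    lf <- structure(list(gains = gains, channel_order = montage$channel_names,
                         source_order = vapply(sources, `[[`, "", "label"),
                         condition_number = NA_real_),
                    class = "mmn_leadfield")
  }
  .lf_cache[[key]] <- lf
  lf
}

#' Simulate a whole cohort
#'
#' Generates one raw recording per subject and either collects them (only
#' advisable for small designs) or streams each to `callback(raw, profile)`
#' so that cohort-scale simulation never holds more than one recording in
#' memory.
#'
#' @param design An `mmn_design`.
#' @param seq An `mmn_sequence` shared by all subjects (default: generated
#'   from the design's master seed).
#' @param montage,head Geometry (defaults: [build_montage()],
#'   [head_model()]).
#' @param seed Cohort seed (default: the design's master seed).
#' @param callback Optional `function(raw, profile)`; when given, recordings
#'   are not retained.
#' @return List with `profiles` (the cohort metadata table) and
#'   `recordings` (list of `mmn_raw`, or NULL when a callback is used).
#' @export
simulate_cohort <- function(design, seq = NULL, montage = build_montage(),
                            head = head_model(), seed = design$master_seed,
                            callback = NULL) {
  seq <- seq %||% generate_sequence(seed)
  profiles <- sample_profiles(design, seed)
  shape <- design$sim$mmn_shape %||% "wavelet"
  recordings <- if (is.null(callback)) vector("list", nrow(profiles)) else NULL
  for (i in seq_len(nrow(profiles))) {
    raw <- simulate_subject(profiles[i, ], seq, montage, head, shape = shape)
    if (is.null(callback)) {
      recordings[[i]] <- raw
    } else {
      callback(raw, profiles[i, ])
    }
  }
  list(profiles = profiles, recordings = recordings)
}
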