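# Cohort design, profile sampling and raw-EEG simulation.

test_that("default design instantiates the study sample structure", {
  d <- default_study_design()
  expect_identical(d$groups$n, c(50L, 74L, 74L, 13L))
  expect_identical(sum(d$groups$n[-1]), 161L)
  expect_identical(sum(d$groups$transitions), 15L)
  expect_equal(d$source_moments$RS3["CON", ], c(mean = 13.95, sd = 7.17))
  expect_equal(d$source_moments$RS3["BS", "mean"], 7.72, ignore_attr = TRUE)
  expect_equal(d$transition_moments$transition[["RS3"]], 5.21)
  expect_equal(d$transition_moments$no_transition[["RS3"]], 8.29)
})

test_that("profile sampling reproduces design counts and moments", {
  d <- default_study_design()
  p <- sample_profiles(d, 11)
  expect_identical(nrow(p), 211L)
  expect_identical(sum(p$group != "CON"), 161L)
  expect_identical(sum(p$transition), 15L)
  expect_identical(as.integer(table(factor(p$group,
                                           c("CON", "BS", "UHR&BS", "UHR")))),
                   c(50L, 74L, 74L, 13L))
  expect_true(all(p$rs1_amp > 0 & p$rs2_amp > 0 & p$rs3_amp > 0))
  expect_true(all(p$mmn_peak_latency_ms >= 150 &
                    p$mmn_peak_latency_ms <= 250))
  # reproducibility
  expect_identical(sample_profiles(d, 11), p)
})

test_that("amplitude sampler converges to the design mean (law of large numbers)", {
  big <- default_study_design()
  big$groups <- data.frame(group = "CON", n = 10000L, transitions = 0L,
                           stringsAsFactors = FALSE)
  p <- sample_profiles(big, 99)
  expect_lt(abs(mean(p$rs3_amp) - 13.95) / 13.95, 0.02)
  expect_lt(abs(mean(p$rs1_amp) - 14.71) / 14.71, 0.02)
})

test_that("degenerate and infeasible amplitude draws behave as specified", {
  d <- default_study_design()
  d$source_moments$RS1[, "sd"] <- 0
  d$source_moments$RS2[, "sd"] <- 0
  d$source_moments$RS3[, "sd"] <- 0
  d$transition_moments$no_transition_sd[] <- 0
  d$transition_moments$transition_sd[] <- 0
  p <- sample_profiles(d, 1)
  con <- p[p$group == "CON", ]
  expect_true(all(con$rs3_amp == 13.95))
  expect_error(mmnsource:::.rtnorm_floor(5, 0.1, 0.5, 0.5), "infeasible")
  expect_error(mmnsource:::.rtnorm_floor(5, 0.3, 0, 0.5), "below the positive floor")
})

test_that("source templates calibrate the deviant-minus-standard peak exactly", {
  prof <- fx_profile()
  std <- source_response_templates(prof, "standard")
  expect_true(all(std[, "RS3"] == 0))
  for (kind in c("duration", "frequency", "intensity")) {
    dev <- source_response_templates(prof, kind)
    mmn <- dev - std
    suffix <- if (kind == "duration") "" else paste0("_", kind)
    t_ms <- (seq_len(nrow(dev)) - 1) * 2
    for (srcname in c("RS1", "RS2", "RS3")) {
      amp <- prof[[paste0(tolower(srcname), "_amp", suffix)]]
      expect_equal(max(abs(mmn[, srcname])), amp, tolerance = 1e-12)
      expect_equal(t_ms[which.max(abs(mmn[, srcname]))],
                   prof$mmn_peak_latency_ms)
    }
  }
  # support confined to the 0-400 ms epoch
  expect_identical(nrow(std), 200L)
})

test_that("noiseless simulation reproduces the projected MMN template at deviant epochs", {
  prof <- fx_profile(noise_rms = 0, blink_rate = 0)
  seqq <- fx_small_sequence()
  montage <- fx_montage(); head <- fx_head()
  raw <- simulate_subject(prof, seqq, montage, head, seed = 21)
  expect_true(all(is.finite(raw$data)))
  # epoch without filtering; baseline interval precedes the response support
  ep <- segment(raw)
  ev <- average_by_condition(ep, c("standard", "duration"))
  d <- compute_difference(ev$duration, ev$standard)
  # expected: lead-field projection (FCz reference) of the MMN component
  lf <- mmnsource:::assemble_leadfield_cached(head, default_sources(),
                                             montage, reference = "FCz")
  lfa <- mmnsource:::assemble_leadfield_cached(head, default_sources(),
                                              montage)
  ori <- mmnsource:::mmn_orientations(lfa, montage)
  std <- source_response_templates(prof, "standard")
  dev <- source_response_templates(prof, "duration")
  proj <- sapply(1:3, function(k) lf$gains[, 3 * (k - 1) + 1:3] %*% ori[, k])
  expected <- (dev - std) %*% t(proj)
  got <- d$waveform[ep$time_ms >= 0, ]
  expect_lt(max(abs(got - expected)), 1e-9)
})

test_that("raising the frontal amplitude raises the noiseless scalp MMN at Fz", {
  seqq <- fx_small_sequence()
  prof_lo <- fx_profile(); prof_lo$rs3_amp <- 5
  prof_hi <- prof_lo; prof_hi$rs3_amp <- 15
  mag <- function(prof) {
    raw <- simulate_subject(prof, seqq, fx_montage(), fx_head(), seed = 2)
    res <- process_subject(raw, fx_model())
    surf <- res$surface
    abs(surf$amplitude_uv[surf$condition == "duration" &
                            surf$channel == "Fz"])
  }
  expect_gt(mag(prof_hi), mag(prof_lo))
})

test_that("simulation is bit-identical under a fixed seed", {
  prof <- fx_profile(noise_rms = 2, blink_rate = 0.1)
  seqq <- fx_small_sequence()
  r1 <- simulate_subject(prof, seqq, fx_montage(), fx_head(), seed = 13)
  r2 <- simulate_subject(prof, seqq, fx_montage(), fx_head(), seed = 13)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_subject(prof, seqq, fx_montage(), fx_head(), seed = 14)
  expect_false(identical(r3$data, r1$data))
})

test_that("simulated noise has the calibrated RMS after the analysis band-pass", {
  set.seed(6)
  n <- 50000L
  noise <- mmnsource:::.simulate_noise(n, 32L, 500, 4, fx_montage())
  filtered <- mmnsource:::fft_bandpass(noise, 500, 1, 20)
  rms <- sqrt(mean(filtered^2))
  expect_lt(abs(rms - 4) / 4, 0.15)
})

test_that("cohort simulation streams subjects through a callback", {
  d <- default_study_design()
  d$groups$n <- c(2L, 1L, 1L, 1L)
  d$groups$transitions <- c(0L, 0L, 1L, 0L)
  seqq <- fx_small_sequence()
  seen <- character()
  res <- simulate_cohort(d, seq = seqq, seed = 9,
                         callback = function(raw, profile) {
                           seen <<- c(seen, profile$subject_id)
                           expect_s3_class(raw, "mmn_raw")
                         })
  expect_null(res$recordings)
  expect_identical(seen, res$profiles$subject_id)
  expect_identical(nrow(res$profiles), 5L)
})
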