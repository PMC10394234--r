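# Preprocessing: re-referencing, filtering, segmentation, rejection,
# gating, averaging.

# Raw object with constant per-channel values (EEG channels get 1..31, EOG
# gets 100) and a handful of markers.
toy_raw <- function(nsamp = 2000L, values = NULL) {
  m <- fx_montage()
  eeg <- mmnsource:::eeg_channels(m)
  v <- numeric(32)
  v[eeg] <- values %||% seq_along(eeg)
  v[-eeg] <- 100
  data <- matrix(rep(v, each = nsamp), nsamp, 32)
  colnames(data) <- m$channel_names
  markers <- data.frame(kind = c("standard", "standard", "duration"),
                        onset_ms = c(0, 500, 1000))
  raw_recording(data, m, markers, first_onset_sample = 500L)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("average re-referencing centers the EEG channels and spares the EOG", {
  raw <- toy_raw()
  eeg <- mmnsource:::eeg_channels(raw$montage)
  rr <- rereference_average(raw)
  expect_lt(max(abs(rowMeans(rr$data[, eeg]))), 1e-9)
  expect_equal(rr$data[1, eeg], seq_along(eeg) - mean(seq_along(eeg)),
               ignore_attr = TRUE)
  expect_true(all(rr$data[, -eeg] == 100))
  # idempotent
  rr2 <- rereference_average(rr)
  expect_equal(rr2$data, rr$data, tolerance = 1e-12)
  # constant offset on every channel is removed from the EEG set
  raw2 <- toy_raw()
  raw2$data[, eeg] <- raw2$data[, eeg] + 57.3
  expect_equal(rereference_average(raw2)$data[, eeg], rr$data[, eeg],
               tolerance = 1e-9)
})

test_that("zero-phase band-pass has the specified frequency response", {
  m <- fx_montage()
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  mk <- data.frame(kind = "standard", onset_ms = 0)
  mk_raw <- function(x) {
    data <- matrix(rep(x, 32), length(x), 32)
    colnames(data) <- m$channel_names
    raw_recording(data, m, mk, first_onset_sample = 2500L)
  }
  core <- 3000:7000   # avoid edges
  # 10 Hz tone passes with gain >= 0.9
  y10 <- bandpass(mk_raw(sin(2 * pi * 10 * t)))$data[, 1]
  g10 <- max(abs(y10[core]))
  expect_gte(g10, 0.9)
  expect_lte(g10, 1.01)
  # 100 Hz attenuated by >= 20 dB
  y100 <- bandpass(mk_raw(sin(2 * pi * 100 * t)))$data[, 1]
  expect_lt(max(abs(y100[core])), 10^(-20 / 20))
  # DC removed
  ydc <- bandpass(mk_raw(rep(5, length(t))))$data[, 1]
  expect_lt(abs(mean(ydc[core])), 1e-3)
  # white noise: the 12 dB/octave net low-pass leaves only a small fraction
  # of spectral power above 40 Hz
  set.seed(1)
  yw <- bandpass(mk_raw(rnorm(length(t))))$data[, 1]
  sp <- Mod(fft(yw))^2
  f <- mmnsource:::fft_freqs(length(yw), fs)
  expect_lt(sum(sp[abs(f) > 40]) / sum(sp), 0.05)
  # invalid cutoffs
  expect_error(bandpass(mk_raw(t), low_hz = 1, high_hz = 300), "Nyquist")
  expect_error(bandpass(mk_raw(t), low_hz = 30, high_hz = 20), "invalid")
})

test_that("zero-phase filtering preserves the latency of a transient", {
  m <- fx_montage()
  fs <- 500
  n <- 5000L
  x <- numeric(n)
  centre <- 2500L
  x[(centre - 75):(centre + 75)] <-
    mmnsource:::.mmn_wavelet(seq(-150, 150, by = 2), 0)
  data <- matrix(rep(x, 32), n, 32)
  colnames(data) <- m$channel_names
  raw <- raw_recording(data, m, data.frame(kind = "standard", onset_ms = 0),
                       first_onset_sample = 1L)
  y <- bandpass(raw)$data[, 1]
  expect_equal(which.max(abs(y)), centre)
})

test_that("segmentation produces baseline-corrected 250-sample epochs", {
  seqq <- fx_small_sequence()
  prof <- fx_profile()
  raw <- simulate_subject(prof, seqq, fx_montage(), fx_head(), seed = 1)
  ep <- segment(raw)
  expect_identical(dim(ep$trials), c(250L, nrow(seqq$events), 32L))
  expect_identical(range(ep$time_ms), c(-100, 398))
  expect_identical(sum(ep$time_ms < 0), 50L)
  # constant channels yield all-zero epochs after baseline correction
  ep0 <- segment(toy_raw())
  expect_lt(max(abs(ep0$trials)), 1e-12)
  expect_identical(dim(ep0$trials)[2], 3L)
})

test_that("markers too close to the recording edge are flagged, not dropped", {
  raw <- toy_raw(nsamp = 700L)
  raw$markers <- data.frame(kind = c("standard", "standard"),
                            onset_ms = c(0, 300))
  # second marker: onset sample 650, needs 200 post samples -> edge
  ep <- segment(raw)
  expect_identical(ep$rejection_reason, c("none", "edge"))
  expect_identical(ep$accepted, c(TRUE, FALSE))
  ep <- reject_artifacts(ep)
  expect_identical(ep$rejection_reason[2], "edge")
  expect_false(ep$accepted[2])
})

test_that("artifact rejection applies the amplitude and EOG rules", {
  m <- fx_montage()
  eog <- match(m$eog_channel, m$channel_names)
  trials <- array(0, c(250, 4, 32))
  trials[120, 2, 5] <- 130        # EEG amplitude violation
  trials[100, 3, 5] <- 119        # below threshold
  trials[100:140, 4, eog] <- 80   # EOG blink
  ep <- fx_epochs(trials, rep("standard", 4), m)
  ep <- reject_artifacts(ep)
  expect_identical(ep$accepted, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(ep$rejection_reason,
                   c("none", "amplitude", "none", "eog"))
  # idempotent
  expect_identical(reject_artifacts(ep)$accepted, ep$accepted)
  # EOG channel amplitude does not trigger the EEG amplitude rule
  trials2 <- array(0, c(250, 1, 32))
  trials2[10, 1, eog] <- 200
  ep2 <- reject_artifacts(fx_epochs(trials2, "standard", m))
  expect_identical(ep2$rejection_reason, "eog")
})

test_that("lowering the amplitude threshold never increases accepted counts", {
  set.seed(3)
  trials <- array(rnorm(250 * 30 * 32, 0, 40), c(250, 30, 32))
  ep <- fx_epochs(trials, rep("standard", 30))
  counts <- vapply(c(200, 150, 120, 90, 60),
                   function(th) sum(reject_artifacts(ep,
                                                     amp_threshold_uv = th,
                                                     eog_threshold_uv = Inf)$accepted),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("subject gate includes at exactly 60% and excludes strictly below", {
  ep <- fx_epochs(array(0, c(250, 2400, 32)), rep("standard", 2400))
  ep$accepted[] <- c(rep(TRUE, 1440), rep(FALSE, 960))
  g <- subject_gate(ep)
  expect_equal(g$ratio, 0.6)
  expect_true(g$include)
  ep$accepted[1440] <- FALSE
  expect_false(subject_gate(ep)$include)
  ep_all <- fx_epochs(array(0, c(250, 10, 32)), rep("standard", 10))
  expect_equal(subject_gate(ep_all)$ratio, 1)
  ep0 <- fx_epochs(array(0, c(250, 1, 32)), "standard")
  ep0$accepted <- logical(0)
  expect_error(subject_gate(ep0), "zero trials")
})

test_that("condition averages use accepted trials only and are order-invariant", {
  set.seed(8)
  trials <- array(rnorm(250 * 20 * 32), c(250, 20, 32))
  cond <- rep(c("standard", "duration"), each = 10)
  ep <- fx_epochs(trials, cond)
  ep$accepted[c(3, 15)] <- FALSE
  ev <- average_by_condition(ep)
  # brute-force oracle over the accepted subset
  sel <- which(cond == "standard" & ep$accepted)
  oracle <- apply(trials[, sel, ], c(1, 3), mean)
  expect_equal(unname(ev$standard$mean_waveform), oracle, tolerance = 1e-12)
  expect_identical(ev$standard$n_trials_accepted, length(sel))
  # permuting trials leaves averages unchanged
  perm <- sample(20)
  ep2 <- fx_epochs(trials[, perm, ], cond[perm])
  ep2$accepted <- ep$accepted[perm]
  ev2 <- average_by_condition(ep2)
  expect_equal(ev2$standard$mean_waveform, ev$standard$mean_waveform,
               tolerance = 1e-12)
  # identical trials average to any trial; antisymmetric pair cancels
  tt <- array(0, c(250, 2, 32))
  tt[, 1, ] <- trials[, 1, ]
  tt[, 2, ] <- trials[, 1, ]
  expect_equal(unname(average_by_condition(
    fx_epochs(tt, rep("x", 2)))$x$mean_waveform),
    trials[, 1, ], tolerance = 1e-12)
  tt[, 2, ] <- -tt[, 1, ]
  expect_lt(max(abs(average_by_condition(
    fx_epochs(tt, rep("x", 2)))$x$mean_waveform)), 1e-12)
  # empty condition errors with the condition name
  ep$accepted[cond == "duration"] <- FALSE
  expect_error(average_by_condition(ep), "duration")
})
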