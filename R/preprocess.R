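# ERP preprocessing: re-reference, filter, epoch, baseline, artifact
# rejection, subject gating, condition averaging.
#
# Processing order is fixed: average reference -> 1-20 Hz zero-phase filter
# -> segmentation with baseline correction -> artifact rejection -> 60%
# acceptance gate -> per-condition averaging.

# ---- raw container -------------------------------------------------------

#' Construct a raw recording object
#'
#' @param data samples x channels matrix, microvolts.
#' @param montage An `mmn_montage`; columns of `data` follow
#'   `montage$channel_names`.
#' @param markers data.frame with columns `kind` and `onset_ms`; onsets are
#'   relative to `first_onset_sample` (the sample index, 1-based, at which
#'   stimulus time 0 occurs).
#' @param fs_hz Sampling rate (500).
#' @param first_onset_sample Sample index of stimulus time zero.
#' @param reference Current reference of the data (`"FCz"` or `"average"`).
#' @param subject_id Optional identifier.
#' @export
raw_recording <- function(data, montage, markers, fs_hz = 500,
                          first_onset_sample = 1L, reference = "FCz",
                          subject_id = NA_character_) {
  stopifnot(ncol(data) == length(montage$channel_names))
  if (!is.finite(sum(data))) stop("raw data contain non-finite samples")
  structure(list(data = data, montage = montage, markers = markers,
                 fs_hz = fs_hz, first_onset_sample = as.integer(first_onset_sample),
                 reference = reference, subject_id = subject_id),
            class = "mmn_raw")
}

#' @export
print.mmn_raw <- function(x, ...) {
  cat("<mmn_raw>", ncol(x$data), "channels x", nrow(x$data), "samples @",
      x$fs_hz, "Hz,", nrow(x$markers), "markers, reference", x$reference,
      "\n")
  invisible(x)
}

# Sample index (1-based) of each marker onset.
marker_samples <- function(raw) {
  raw$first_onset_sample + as.integer(round(raw$markers$onset_ms / 1000 * raw$fs_hz))
}

# ---- re-referencing ------------------------------------------------------

#' Re-reference a recording to the average of the scalp EEG channels
#'
#' The mean over EEG channels (EOG excluded) is subtracted from every EEG
#' channel at every sample; the EOG channel is left unchanged. Idempotent.
#'
#' @param raw An `mmn_raw`.
#' @return The re-referenced `mmn_raw` (reference `"average"`).
#' @export
rereference_average <- function(raw) {
  eeg <- eeg_channels(raw$montage)
  dn <- dimnames(raw$data)
  raw$data <- cpp_subtract_rowmean(raw$data, eeg)
  dimnames(raw$data) <- dn
  raw$reference <- "average"
  raw
}

# ---- zero-phase band-pass ------------------------------------------------

# Magnitude response of the band-pass: 2nd-order Butterworth high-pass at
# `low_hz` times 2nd-order Butterworth low-pass at `high_hz`, 12 dB/octave
# each. Applied with zero phase in the frequency domain, so the net response
# has exactly this slope (no slope doubling from forward-backward passes).
bandpass_response <- function(f_hz, low_hz = 1, high_hz = 20) {
  af <- abs(f_hz)
  hp <- ifelse(af == 0, 0, (af / low_hz)^2 / sqrt(1 + (af / low_hz)^4))
  lp <- 1 / sqrt(1 + (af / high_hz)^4)
  hp * lp
}

# Fourier frequencies (two-sided) for an FFT of length nfft.
fft_freqs <- function(nfft, fs_hz) {
  c(0:(nfft %/% 2), -rev(seq_len(nfft - nfft %/% 2 - 1))) * fs_hz / nfft
}

# Zero-phase filter a samples x channels matrix (padded FFT; compiled).
fft_bandpass <- function(x, fs_hz, low_hz, high_hz) {
  n <- nrow(x)
  nfft <- nextn(n + 4L * as.integer(fs_hz), c(2, 3, 5))  # pad >= 4 s for filter tails
  H <- bandpass_response(fft_freqs(nfft, fs_hz), low_hz, high_hz)
  out <- cpp_fft_filter(x, H)
  dimnames(out) <- dimnames(x)
  out
}

#' Band-pass filter a recording (1-20 Hz, zero phase)
#'
#' Zero-phase filter with the magnitude response of a 2nd-order Butterworth
#' high-pass at `low_hz` and a 2nd-order Butterworth low-pass at `high_hz`
#' (12 dB/octave each), applied in the frequency domain so peak latencies
#' are not distorted.
#'
#' @param raw An `mmn_raw`.
#' @param low_hz High-pass cut-off (default 1).
#' @param high_hz Low-pass cut-off (default 20).
#' @export
bandpass <- function(raw, low_hz = 1, high_hz = 20) {
  nyq <- raw$fs_hz / 2
  if (low_hz <= 0 || high_hz <= low_hz) stop("invalid cut-off frequencies")
  if (high_hz >= nyq) {
    stop("high cut-off ", high_hz, " Hz is not below the Nyquist frequency (",
         nyq, " Hz)")
  }
  raw$data <- fft_bandpass(raw$data, raw$fs_hz, low_hz, high_hz)
  raw
}

# ---- segmentation --------------------------------------------------------

#' Segment a recording into baseline-corrected epochs
#'
#' One 500 ms epoch per marker (-100 to +400 ms around stimulus onset at
#' 500 Hz, 250 samples). The mean of the -100..0 ms interval is subtracted
#' per channel and trial. Markers too close to a recording edge yield trials
#' flagged as rejected with reason `"edge"` rather than being dropped.
#'
#' @param raw An `mmn_raw`.
#' @param seq Optional `mmn_sequence`; defaults to the markers stored in
#'   `raw`.
#' @param pre_ms,post_ms Epoch limits around onset (defaults 100 / 400 ms).
#' @return An `mmn_epochs`: array `trials` (samples x trials x channels),
#'   `time_ms`, `condition`, `accepted`, `rejection_reason`.
#' @export
segment <- function(raw, seq = NULL, pre_ms = 100, post_ms = 400) {
  markers <- if (is.null(seq)) raw$markers else seq$events
  fs <- raw$fs_hz
  npre <- as.integer(round(pre_ms / 1000 * fs))
  npost <- as.integer(round(post_ms / 1000 * fs))
  nsamp <- npre + npost
  on <- raw$first_onset_sample +
    as.integer(round(markers$onset_ms / 1000 * fs))
  ok <- on - npre >= 1 & on + npost - 1 <= nrow(raw$data)
  trials <- cpp_segment(raw$data, on, npre, npost, as.integer(ok))
  structure(list(
    trials = trials,
    time_ms = (seq_len(nsamp) - npre - 1L) * 1000 / fs,
    condition = markers$kind,
    accepted = ok,
    rejection_reason = ifelse(ok, "none", "edge"),
    montage = raw$montage, fs_hz = fs
  ), class = "mmn_epochs")
}

#' @export
print.mmn_epochs <- function(x, ...) {
  cat("<mmn_epochs>", dim(x$trials)[2], "trials x", dim(x$trials)[3],
      "channels,", dim(x$trials)[1], "samples (",
      min(x$time_ms), "..", max(x$time_ms), "ms );",
      sum(x$accepted), "accepted\n")
  invisible(x)
}

# ---- artifact rejection --------------------------------------------------

#' Reject artifact-contaminated epochs
#'
#' A trial is rejected when any EEG channel exceeds `amp_threshold_uv` in
#' absolute post-baseline amplitude, or when the EOG channel's peak-to-peak
#' amplitude within the epoch exceeds `eog_threshold_uv`. Flags are
#' recomputed from the data, so the operation is idempotent; trials already
#' flagged `"edge"` stay rejected.
#'
#' @param epochs An `mmn_epochs`.
#' @param amp_threshold_uv Absolute amplitude threshold (default 120).
#' @param eog_threshold_uv EOG peak-to-peak threshold (default 60).
#' @export
reject_artifacts <- function(epochs, amp_threshold_uv = 120,
                             eog_threshold_uv = 60) {
  d <- dim(epochs$trials)
  eeg <- eeg_channels(epochs$montage)
  eog <- match(epochs$montage$eog_channel, epochs$montage$channel_names)
  st <- cpp_trial_stats(epochs$trials, d[1], d[2], d[3],
                        as.integer(eeg), as.integer(eog))
  amp_bad <- st[, 1] > amp_threshold_uv
  eog_bad <- if (is.na(eog)) rep(FALSE, d[2]) else st[, 2] > eog_threshold_uv
  edge <- epochs$rejection_reason == "edge"
  epochs$accepted <- !edge & !amp_bad & !eog_bad
  epochs$rejection_reason <- ifelse(edge, "edge",
    ifelse(amp_bad, "amplitude", ifelse(eog_bad, "eog", "none")))
  epochs
}

#' Subject-level acceptance gate
#'
#' Subjects providing fewer than 60% accepted trials are excluded; a ratio of
#' exactly 0.60 is included (the rule excludes strictly below 60%).
#'
#' @param epochs An `mmn_epochs` after rejection.
#' @param min_ratio Acceptance threshold (default 0.6).
#' @return List with `ratio`, `n_accepted`, `n_total`, `include`.
#' @export
subject_gate <- function(epochs, min_ratio = 0.6) {
  n <- length(epochs$accepted)
  if (n == 0) stop("subject gate undefined for zero trials")
  ratio <- sum(epochs$accepted) / n
  list(ratio = ratio, n_accepted = sum(epochs$accepted), n_total = n,
       include = ratio >= min_ratio)
}

# ---- averaging -----------------------------------------------------------

#' Average accepted trials by condition
#'
#' @param epochs An `mmn_epochs` after rejection.
#' @param conditions Conditions to average (default: all present).
#' @return Named list of `mmn_evoked` objects (`condition`, `mean_waveform`
#'   samples x channels, `n_trials_accepted`, `time_ms`).
#' @export
average_by_condition <- function(epochs, conditions = NULL) {
  conditions <- conditions %||% unique(epochs$condition)
  d <- dim(epochs$trials)
  out <- lapply(conditions, function(cond) {
    sel <- which(epochs$condition == cond & epochs$accepted)
    if (!length(sel)) {
      stop("condition '", cond, "' has no accepted trials")
    }
    m <- cpp_cond_mean(epochs$trials, d[1], d[2], d[3], as.integer(sel))
    colnames(m) <- epochs$montage$channel_names
    structure(list(condition = cond, mean_waveform = m,
                   n_trials_accepted = length(sel),
                   time_ms = epochs$time_ms, montage = epochs$montage),
              class = "mmn_evoked")
  })
  names(out) <- conditions
  out
}

#' @export
print.mmn_evoked <- function(x, ...) {
  cat("<mmn_evoked>", x$condition, "-", x$n_trials_accepted,
      "trials averaged\n")
  invisible(x)
}

#' Per-subject preprocessing QC report
#'
#' @param epochs An `mmn_epochs` after rejection.
#' @return data.frame: per condition accepted/total counts plus rejection
#'   reasons, and the gate decision as an attribute.
#' @export
qc_report <- function(epochs) {
  conds <- unique(epochs$condition)
  df <- do.call(rbind, lapply(conds, function(cond) {
    sel <- epochs$condition == cond
    data.frame(condition = cond, n_total = sum(sel),
               n_accepted = sum(sel & epochs$accepted),
               n_amplitude = sum(sel & epochs$rejection_reason == "amplitude"),
               n_eog = sum(sel & epochs$rejection_reason == "eog"),
               n_edge = sum(sel & epochs$rejection_reason == "edge"))
  }))
  attr(df, "gate") <- subject_gate(epochs)
  df
}
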