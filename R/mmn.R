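# Sensor-level MMN: difference waveforms and windowed peak measures.

.analysis_electrodes <- c("Fz", "F3", "F4", "Cz", "C3", "C4")

#' Deviant-minus-standard difference waveform
#'
#' @param deviant,standard `mmn_evoked` objects with matching channel order
#'   and time axes.
#' @return An `mmn_diff`: `condition`, `waveform` (samples x channels, uV),
#'   `time_ms`.
#' @export
compute_difference <- function(deviant, standard) {
  if (!identical(colnames(deviant$mean_waveform),
                 colnames(standard$mean_waveform)) ||
      !identical(deviant$time_ms, standard$time_ms)) {
    stop("deviant and standard evoked responses have mismatched channels or time axes")
  }
  structure(list(condition = deviant$condition,
                 waveform = deviant$mean_waveform - standard$mean_waveform,
                 time_ms = deviant$time_ms, montage = deviant$montage),
            class = "mmn_diff")
}

#' @export
print.mmn_diff <- function(x, ...) {
  cat("<mmn_diff>", x$condition, "difference waveform,",
      ncol(x$waveform), "channels\n")
  invisible(x)
}

#' Detect the MMN peak in a difference waveform
#'
#' Returns the most negative sample within the closed search window and its
#' latency; ties are broken by the earliest latency.
#'
#' @param diff An `mmn_diff`.
#' @param channel Channel label.
#' @param window_ms Search window, default `c(150, 250)` ms post-stimulus.
#' @return List with `channel`, `amplitude_uv`, `latency_ms`.
#' @export
detect_peak <- function(diff, channel, window_ms = c(150, 250)) {
  ch <- match(channel, colnames(diff$waveform))
  if (is.na(ch)) stop("channel '", channel, "' not present in the waveform")
  sel <- which(diff$time_ms >= window_ms[1] & diff$time_ms <= window_ms[2])
  if (!length(sel)) stop("peak window lies outside the epoch")
  w <- diff$waveform[sel, ch]
  i <- which.min(w)            # first index on ties -> earliest latency
  list(channel = channel, amplitude_uv = w[i],
       latency_ms = diff$time_ms[sel[i]])
}

#' Windowed peak measures at the six analysis electrodes
#'
#' @param diffs Named list of `mmn_diff` objects (one per deviant
#'   condition).
#' @param channels Electrodes to measure (default Fz, F3, F4, Cz, C3, C4).
#' @param window_ms Peak search window (default 150-250 ms).
#' @return data.frame: condition, channel, amplitude_uv, latency_ms.
#' @export
surface_measures <- function(diffs, channels = .analysis_electrodes,
                             window_ms = c(150, 250)) {
  rows <- lapply(diffs, function(d) {
    do.call(rbind, lapply(channels, function(ch) {
      p <- detect_peak(d, ch, window_ms)
      data.frame(condition = d$condition, channel = ch,
                 amplitude_uv = p$amplitude_uv, latency_ms = p$latency_ms,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a difference waveform
#'
#' Basic base-graphics display of the MMN difference wave at one or more
#' channels, with the peak search window shaded.
#'
#' @param x An `mmn_diff`.
#' @param channels Channels to draw (default Fz).
#' @param window_ms Peak window to indicate.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.mmn_diff <- function(x, channels = "Fz", window_ms = c(150, 250), ...) {
  ch <- match(channels, colnames(x$waveform))
  graphics::matplot(x$time_ms, x$waveform[, ch, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = paste("MMN difference wave -", x$condition), ...)
  graphics::abline(v = window_ms, lty = 3)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = channels, lty = 1,
                   col = seq_along(ch), bty = "n")
  invisible(x)
}
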