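# Electrode montage geometry.
#
# The default layout mirrors a 32-channel extended 10-20 recording cap:
# 31 scalp electrodes plus one infra-orbital EOG electrode (below the right
# eye), recorded against FCz with the ground at AFz. Positions are idealized
# spherical 10-20 angular positions on the scalp sphere, not digitized cap
# coordinates.

# Unit direction vectors (head frame: +x right, +y anterior, +z vertex) for
# the supported labels. FCz is kept for use as the recording reference site.
.electrode_directions <- function() {
  tab <- matrix(c(
    -0.308829,  0.950477, -0.034899,  # Fp1
     0.308829,  0.950477, -0.034899,  # Fp2
    -0.808524,  0.587427, -0.034899,  # F7
    -0.545007,  0.673028,  0.500000,  # F3
     0.000000,  0.719340,  0.694658,  # Fz
     0.545007,  0.673028,  0.500000,  # F4
     0.808524,  0.587427, -0.034899,  # F8
    -0.887888,  0.340828,  0.309017,  # FC5
    -0.374710,  0.374710,  0.848048,  # FC1
     0.374710,  0.374710,  0.848048,  # FC2
     0.887888,  0.340828,  0.309017,  # FC6
    -0.999391,  0.000000, -0.034899,  # T7
    -0.719340,  0.000000,  0.694658,  # C3
     0.000000,  0.000000,  1.000000,  # Cz
     0.719340,  0.000000,  0.694658,  # C4
     0.999391,  0.000000, -0.034899,  # T8
    -0.887888, -0.340828,  0.309017,  # CP5
    -0.374710, -0.374710,  0.848048,  # CP1
     0.374710, -0.374710,  0.848048,  # CP2
     0.887888, -0.340828,  0.309017,  # CP6
    -0.861950, -0.280065, -0.422618,  # TP9
     0.861950, -0.280065, -0.422618,  # TP10
    -0.808524, -0.587427, -0.034899,  # P7
    -0.545007, -0.673028,  0.500000,  # P3
     0.000000, -0.719340,  0.694658,  # Pz
     0.545007, -0.673028,  0.500000,  # P4
     0.808524, -0.587427, -0.034899,  # P8
     0.000000, -0.933580,  0.358368,  # POz
    -0.308829, -0.950477, -0.034899,  # O1
     0.000000, -0.999391, -0.034899,  # Oz
     0.308829, -0.950477, -0.034899,  # O2
     0.249666,  0.898918, -0.359520,  # EOG (below right eye)
     0.000000,  0.390731,  0.920505   # FCz (reference site)
  ), ncol = 3, byrow = TRUE)
  rownames(tab) <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC5", "FC1",
                     "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8", "CP5", "CP1",
                     "CP2", "CP6", "TP9", "TP10", "P7", "P3", "Pz", "P4", "P8",
                     "POz", "O1", "Oz", "O2", "EOG", "FCz")
  # renormalize to unit length (guards against rounding in the frozen table)
  tab / sqrt(rowSums(tab^2))
}

#' Build an electrode montage
#'
#' Constructs the 32-channel recording montage used throughout the pipeline:
#' 31 scalp EEG electrodes on idealized spherical 10-20 positions plus one
#' EOG electrode below the right eye, all on the scalp-shell surface,
#' referenced to FCz.
#'
#' @param layout Layout name. Only `"braincap32"` (the default 32-channel
#'   extended 10-20 layout) is supported.
#' @param scalp_radius_m Scalp sphere radius in metres (default 0.085).
#' @return An object of class `mmn_montage` with elements `channel_names`,
#'   `positions` (32 x 3 matrix, metres), `recording_reference` (`"FCz"`),
#'   `reference_position`, `eog_channel` and `scalp_radius_m`.
#' @examples
#' m <- build_montage()
#' all(c("Fz", "F3", "F4", "Cz", "C3", "C4") %in% m$channel_names)
#' @export
build_montage <- function(layout = "braincap32", scalp_radius_m = 0.085) {
  if (!identical(layout, "braincap32")) {
    stop("unknown montage layout: '", layout, "' (supported: \"braincap32\")")
  }
  dirs <- .electrode_directions()
  ch <- setdiff(rownames(dirs), "FCz")
  montage <- structure(list(
    channel_names = ch,
    positions = dirs[ch, , drop = FALSE] * scalp_radius_m,
    recording_reference = "FCz",
    reference_position = dirs["FCz", ] * scalp_radius_m,
    eog_channel = "EOG",
    scalp_radius_m = scalp_radius_m
  ), class = "mmn_montage")
  montage
}

# Indices of scalp EEG channels (everything except the EOG channel).
eeg_channels <- function(montage) {
  which(montage$channel_names != montage$eog_channel)
}

#' @export
print.mmn_montage <- function(x, ...) {
  cat("<mmn_montage> ", length(x$channel_names), " channels (",
      length(eeg_channels(x)), " EEG + EOG), reference ",
      x$recording_reference, ", scalp radius ",
      x$scalp_radius_m * 1000, " mm\n", sep = "")
  invisible(x)
}

#' Write or read a montage as a plain-text electrode table
#'
#' The table has columns `label`, `x`, `y`, `z` (metres, head frame).
#'
#' @param montage An `mmn_montage`.
#' @param path File path.
#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$channel_names,
                   x = montage$positions[, 1],
                   y = montage$positions[, 2],
                   z = montage$positions[, 3])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname montage_io
#' @export
read_montage <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("label", "x", "y", "z") %in% names(df)))
  pos <- as.matrix(df[, c("x", "y", "z")])
  rownames(pos) <- df$label
  r <- sqrt(rowSums(pos^2))
  base <- build_montage()
  structure(list(
    channel_names = df$label,
    positions = pos,
    recording_reference = "FCz",
    reference_position = base$reference_position,
    eog_channel = if ("EOG" %in% df$label) "EOG" else NA_character_,
    scalp_radius_m = stats::median(r)
  ), class = "mmn_montage")
}

# Validate montage invariants; called by tests and model construction.
check_montage <- function(montage, tol = 1e-9) {
  r <- sqrt(rowSums(montage$positions^2))
  ok_radius <- all(abs(r - montage$scalp_radius_m) < tol)
  ok_unique <- !anyDuplicated(montage$channel_names)
  ok_six <- all(c("Fz", "F3", "F4", "Cz", "C3", "C4") %in% montage$channel_names)
  ok_n <- length(montage$channel_names) == 32L
  list(on_scalp = ok_radius, unique_names = ok_unique,
       analysis_electrodes = ok_six, n32 = ok_n,
       all = ok_radius && ok_unique && ok_six && ok_n)
}
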