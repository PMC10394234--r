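# BrainVision Core format (.vhdr/.vmrk/.eeg): IEEE float-32, multiplexed,
# microvolts. Stimulus markers: S1 = standard, S2 = duration, S3 =
# frequency, S4 = intensity.

.bv_marker_codes <- c(standard = "S  1", duration = "S  2",
                      frequency = "S  3", intensity = "S  4")

#' Write a recording as a BrainVision triplet
#'
#' @param raw An `mmn_raw`.
#' @param basepath Path without extension; `.vhdr`, `.vmrk` and `.eeg` files
#'   are created.
#' @return `basepath`, invisibly.
#' @export
write_brainvision <- function(raw, basepath) {
  base <- basename(basepath)
  nch <- ncol(raw$data)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / raw$fs_hz, scientific = FALSE)),
    "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,%s,1,uV", seq_len(nch), raw$montage$channel_names,
            if (identical(raw$reference, "FCz")) "FCz" else "")
  )
  writeLines(hdr, paste0(basepath, ".vhdr"))
  pos <- marker_samples(raw)
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_along(pos) + 1L,
            .bv_marker_codes[raw$markers$kind], pos)
  )
  writeLines(mrk, paste0(basepath, ".vmrk"))
  con <- file(paste0(basepath, ".eeg"), "wb")
  on.exit(close(con))
  # multiplexed: channels interleaved within each sample
  writeBin(as.numeric(t(raw$data)), con, size = 4, endian = "little")
  invisible(basepath)
}

.bv_parse_ini <- function(lines) {
  kv <- grep("=", lines, fixed = TRUE, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' Read a BrainVision triplet
#'
#' Supports the dialect written by [write_brainvision()]: binary IEEE
#' float-32, multiplexed orientation. Header/marker/data consistency is
#' checked; a truncated or inconsistent `.eeg` file raises a format error.
#'
#' @param basepath Path without extension (or the `.vhdr` path).
#' @param montage Montage to attach (default [build_montage()]); channel
#'   names must match the header.
#' @return An `mmn_raw`.
#' @export
read_brainvision <- function(basepath, montage = build_montage()) {
  basepath <- sub("\\.vhdr$", "", basepath)
  hdr_path <- paste0(basepath, ".vhdr")
  if (!file.exists(hdr_path)) stop("header file not found: ", hdr_path)
  lines <- readLines(hdr_path, warn = FALSE)
  ini <- .bv_parse_ini(lines)
  fmt <- ini[["BinaryFormat"]]
  if (!identical(fmt, "IEEE_FLOAT_32")) {
    stop("unsupported BrainVision binary format dialect: ",
         fmt %||% "<missing>")
  }
  if (!identical(ini[["DataOrientation"]], "MULTIPLEXED")) {
    stop("unsupported data orientation: ", ini[["DataOrientation"]])
  }
  nch <- as.integer(ini[["NumberOfChannels"]])
  fs <- 1e6 / as.numeric(ini[["SamplingInterval"]])
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, "", 1)
  if (length(ch_names) != nch) {
    stop("format error: header declares ", nch, " channels but lists ",
         length(ch_names))
  }
  eeg_path <- paste0(basepath, ".eeg")
  nbytes <- file.size(eeg_path)
  if (is.na(nbytes)) stop("data file not found: ", eeg_path)
  if (nbytes %% (4 * nch) != 0) {
    stop("format error: ", eeg_path, " (", nbytes, " bytes) is not a whole ",
         "number of ", nch, "-channel float-32 samples (truncated file?)")
  }
  nsamp <- nbytes / (4 * nch)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = nsamp * nch, size = 4, endian = "little")
  data <- t(matrix(v, nch, nsamp))
  colnames(data) <- ch_names
  # markers
  mlines <- readLines(paste0(basepath, ".vmrk"), warn = FALSE)
  stim <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", stim), ",")
  codes <- vapply(parts, `[`, "", 2)
  pos <- as.integer(vapply(parts, `[`, "", 3))
  kind <- names(.bv_marker_codes)[match(codes, .bv_marker_codes)]
  first <- if (length(pos)) pos[1] else 1L
  markers <- data.frame(kind = kind,
                        onset_ms = (pos - first) * 1000 / fs,
                        stringsAsFactors = FALSE)
  if (!identical(ch_names, montage$channel_names)) {
    if (all(sort(ch_names) == sort(montage$channel_names))) {
      data <- data[, montage$channel_names, drop = FALSE]
    } else {
      stop("header channels do not match the supplied montage")
    }
  }
  raw_recording(data, montage, markers, fs_hz = fs,
                first_onset_sample = first, reference = "FCz",
                subject_id = basename(basepath))
}

#' Export a stimulus sequence as a standalone BrainVision marker file
#'
#' @param seq An `mmn_sequence`.
#' @param path Output `.vmrk` path.
#' @param fs_hz Sampling rate used to convert onsets to data points.
#' @param data_file DataFile entry recorded in the marker file.
#' @export
write_sequence_vmrk <- function(seq, path, fs_hz = 500,
                                data_file = "unset.eeg") {
  pos <- as.integer(round(seq$events$onset_ms / 1000 * fs_hz)) + 1L
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "", "[Common Infos]", "Codepage=UTF-8",
    paste0("DataFile=", data_file),
    "", "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_along(pos) + 1L,
            .bv_marker_codes[seq$events$kind], pos)
  )
  writeLines(mrk, path)
  invisible(path)
}
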