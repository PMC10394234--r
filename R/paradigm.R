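# Auditory oddball paradigm: constrained pseudo-random stimulus sequences.

.tone_table <- data.frame(
  kind = c("standard", "duration", "frequency", "intensity"),
  tone_freq_hz = c(1000, 1000, 1200, 1000),
  tone_dur_ms = c(100, 50, 100, 100),
  tone_level_db = c(80, 80, 80, 70),
  stringsAsFactors = FALSE
)

#' Tone parameters of the oddball stimuli
#'
#' Standard: 1000 Hz / 100 ms / 80 dB. Deviants differ in exactly one
#' dimension: duration (50 ms), frequency (1200 Hz) or intensity (70 dB).
#' @return data.frame with one row per stimulus kind.
#' @export
tone_parameters <- function() .tone_table

#' Generate a constrained pseudo-random oddball sequence
#'
#' Produces the stimulus sequence of the study paradigm: `n_standard`
#' standards and `n_deviant` deviants of each of three kinds on a fixed
#' 500 ms onset-asynchrony lattice, with at least `min_gap` standards between
#' any two deviants (of any kinds) and the first two events forced to be
#' standards. Deviant slots are drawn uniformly over all gap compositions
#' satisfying the constraint (stars-and-bars sampling), so no deterministic
#' template recurs across seeds.
#'
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param n_standard Number of standards (default 1896).
#' @param n_deviant Number of deviants per kind (default 168).
#' @param soa_ms Stimulus onset asynchrony in ms (default 500).
#' @param min_gap Minimum number of standards between deviants (default 2).
#' @param no_same_kind_adjacent If TRUE, additionally forbids two deviants of
#'   the same kind in direct succession within the deviant subsequence
#'   (stricter reading of "without recurring order"; default FALSE).
#' @return An `mmn_sequence`: data.frame `events` (kind, onset_ms and tone
#'   parameters) plus `soa_ms` and `seed`.
#' @export
generate_sequence <- function(seed = 0L, n_standard = 1896L, n_deviant = 168L,
                              soa_ms = 500L, min_gap = 2L,
                              no_same_kind_adjacent = FALSE) {
  kinds <- c("duration", "frequency", "intensity")
  nd <- 3L * n_deviant
  excess <- n_standard - min_gap * nd
  if (excess < 0) {
    stop("sequence generation infeasible: ", n_standard, " standards cannot ",
         "provide ", min_gap, " -standard gaps for ", nd, " deviants")
  }
  ev <- with_seed(seed, {
    # Compose gaps g_0..g_nd (standards before/between/after deviants),
    # g_0..g_{nd-1} >= min_gap, via uniform stars-and-bars: place nd
    # separators among excess + nd slots.
    sep <- sort(sample.int(excess + nd, nd))
    gaps <- diff(c(0L, sep)) - 1L                 # standards beyond min_gap
    gaps <- c(gaps, excess - sum(gaps))           # trailing standards
    gaps[seq_len(nd)] <- gaps[seq_len(nd)] + min_gap
    labels <- sample(rep(kinds, each = n_deviant))
    if (no_same_kind_adjacent) labels <- .despread_labels(labels)
    kind <- character(n_standard + nd)
    # deviant i sits after gaps[1..i] standards and (i-1) previous deviants
    pos <- cumsum(gaps[seq_len(nd)]) + seq_len(nd)
    kind[] <- "standard"
    kind[pos] <- labels
    kind
  })
  events <- data.frame(kind = ev,
                       onset_ms = (seq_along(ev) - 1L) * soa_ms,
                       stringsAsFactors = FALSE)
  events <- merge(events, .tone_table, by = "kind", sort = FALSE)
  events <- events[order(events$onset_ms), ]
  rownames(events) <- NULL
  structure(list(events = events, soa_ms = soa_ms, seed = seed),
            class = "mmn_sequence")
}

# Bounded-retry swap repair removing same-kind adjacencies in the deviant
# label order.
.despread_labels <- function(labels, max_iter = 10000L) {
  n <- length(labels)
  for (it in seq_len(max_iter)) {
    bad <- which(labels[-1] == labels[-n])
    if (!length(bad)) return(labels)
    i <- bad[1] + 1L
    j <- sample.int(n, 1L)
    ok <- function(v, k) (k == 1 || v[k] != v[k - 1]) && (k == n || v[k] != v[k + 1])
    cand <- labels
    cand[c(i, j)] <- cand[c(j, i)]
    if (ok(cand, i) && ok(cand, j)) labels <- cand
  }
  stop("could not remove same-kind deviant adjacencies after ", max_iter,
       " swaps")
}

#' @export
print.mmn_sequence <- function(x, ...) {
  tab <- table(x$events$kind)
  cat("<mmn_sequence>", nrow(x$events), "events, SOA", x$soa_ms, "ms, seed",
      x$seed, "\n  ")
  cat(paste(names(tab), as.integer(tab), sep = "="), "\n")
  invisible(x)
}

#' Validate an oddball sequence against the paradigm constraints
#'
#' Each constraint is reported independently; the function never errors.
#'
#' @param seq An `mmn_sequence` (or a compatible list with an `events`
#'   data.frame and `soa_ms`).
#' @param n_standard,n_deviant,soa_ms,min_gap Expected design constants.
#' @return List of logical checks (`counts`, `gap`, `onset_lattice`,
#'   `leading_standards`, `tone_table`) plus `all`.
#' @export
validate_sequence <- function(seq, n_standard = 1896L, n_deviant = 168L,
                              soa_ms = 500L, min_gap = 2L) {
  ev <- seq$events
  kind <- ev$kind
  counts_ok <- sum(kind == "standard") == n_standard &&
    all(vapply(c("duration", "frequency", "intensity"),
               function(k) sum(kind == k) == n_deviant, logical(1)))
  is_dev <- kind != "standard"
  dv <- which(is_dev)
  gap_ok <- if (length(dv) > 1) all(diff(dv) > min_gap) else TRUE
  lead_ok <- length(dv) == 0 || dv[1] > min_gap
  onsets <- ev$onset_ms
  lattice_ok <- length(onsets) == 0 ||
    (onsets[1] == 0 && (length(onsets) < 2 || all(diff(onsets) == soa_ms)))
  tt <- merge(ev, .tone_table, by = "kind", suffixes = c("", ".ref"))
  tone_ok <- all(tt$tone_freq_hz == tt$tone_freq_hz.ref) &&
    all(tt$tone_dur_ms == tt$tone_dur_ms.ref) &&
    all(tt$tone_level_db == tt$tone_level_db.ref)
  out <- list(counts = counts_ok, gap = gap_ok && lead_ok,
              onset_lattice = lattice_ok, leading_standards = lead_ok,
              tone_table = tone_ok)
  out$all <- all(unlist(out))
  out
}

#' Export a sequence as TSV (kind, onset_ms)
#' @param seq An `mmn_sequence`.
#' @param path Output path.
#' @export
write_sequence_tsv <- function(seq, path) {
  write.table(seq$events[, c("kind", "onset_ms")], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
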