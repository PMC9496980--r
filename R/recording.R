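# EEG recordings, spike markers, and constraint windows.
#
# Conventions (fixed throughout the package):
#   * sample i (1-based in R) covers continuous time [(i-1)/fs, i/fs)
#   * marker times are continuous seconds from recording start
#   * seconds -> samples by round-half-away-from-zero
#   * all intervals are half-open [start, stop) in 0-based sample indices
#     (converted to 1-based ranges only at the point of subsetting)

#' Standard 10-20 montage labels (19 channels)
#'
#' Labels and schematic 2-D positions (unit head circle, nose up) for the
#' classic 19-electrode 10-20 montage. Positions are used only to build and
#' plot smooth scalp topographies, never for source localization.
#'
#' @return data.frame with columns `label`, `x`, `y`.
#' @export
montage_1020 <- function() {
  data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6", "O1", "O2"),
    x = c(-0.31, 0.31, -0.81, -0.36, 0, 0.36, 0.81,
          -1, -0.5, 0, 0.5, 1,
          -0.81, -0.36, 0, 0.36, 0.81, -0.31, 0.31),
    y = c(0.95, 0.95, 0.59, 0.55, 0.5, 0.55, 0.59,
          0, 0, 0, 0, 0,
          -0.59, -0.55, -0.5, -0.55, -0.59, -0.95, -0.95),
    stringsAsFactors = FALSE
  )
}

#' Construct a validated EEG recording
#'
#' @param data numeric matrix, channels in rows, samples in columns (microvolt).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of unique channel labels, one per row.
#'   Standard 10-20 labels are recognized case-insensitively; unknown labels are
#'   accepted with a warning (the montage only affects plotting, not analysis).
#' @param reference reference electrode label (metadata only).
#' @param condition_tag free-form condition label, e.g. `"pre_real"`.
#' @return object of class `"eeg_recording"`: a list with elements `data`,
#'   `fs`, `channel_names`, `reference`, `condition_tag`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(4000), 2), fs = 1000,
#'                      channel_names = c("C3", "C4"))
#' rec
#' @export
eeg_recording <- function(data, fs, channel_names = NULL,
                          reference = "FCz", condition_tag = "") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)")
  nch <- nrow(data); ns <- ncol(data)
  if (nch < 2L) stop("at least 2 channels required, got ", nch)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  if (ns < fs) stop("recording shorter than 1 s: ", ns, " samples at ", fs, " Hz")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nch)
    stop("length(channel_names) = ", length(channel_names),
         " but data has ", nch, " channels")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite samples in channel(s): ",
         paste(channel_names[bad], collapse = ", "))
  known <- tolower(montage_1020()$label)
  unknown <- channel_names[!(tolower(channel_names) %in% known)]
  if (length(unknown) && any(grepl("^(ch|sig|src|res)", tolower(unknown)) == FALSE))
    warning("channel label(s) not in the 10-20 vocabulary: ",
            paste(unknown, collapse = ", "), " (accepted; plotting only)")
  dimnames(data) <- list(channel_names, NULL)
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 reference = reference, condition_tag = condition_tag),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  reference:", x$reference,
      if (nzchar(x$condition_tag)) paste0(" condition: ", x$condition_tag) else "",
      "\n")
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Construct validated spike markers
#'
#' Spike-apex times defining the functional-constraint windows of the source
#' extraction: each window spans `window_before_s` seconds before the apex up
#' to `window_after_s` after it. The defaults give the 4 ms rising-spike
#' interval (apex sample excluded under the half-open convention).
#'
#' @param times_s strictly increasing spike-apex times, seconds from start.
#' @param window_before_s constraint window length before each apex (s).
#' @param window_after_s constraint window length after each apex (s).
#' @return object of class `"spike_markers"`.
#' @export
spike_markers <- function(times_s, window_before_s = 0.004,
                          window_after_s = 0) {
  times_s <- as.numeric(times_s)
  if (!length(times_s)) stop("no marker times given")
  if (any(!is.finite(times_s))) stop("non-finite marker times")
  if (is.unsorted(times_s, strictly = TRUE))
    stop("marker times must be strictly increasing with no duplicates")
  if (window_before_s < 0 || window_after_s < 0 ||
      window_before_s + window_after_s <= 0)
    stop("window lengths must be nonnegative with positive total")
  structure(list(times_s = times_s, window_before_s = window_before_s,
                 window_after_s = window_after_s),
            class = "spike_markers")
}

#' @export
print.spike_markers <- function(x, ...) {
  cat(sprintf("<spike_markers> %d events in [%.3f, %.3f] s, window -%g/+%g ms\n",
              length(x$times_s), min(x$times_s), max(x$times_s),
              1000 * x$window_before_s, 1000 * x$window_after_s))
  invisible(x)
}

#' Constraint windows in sample indices
#'
#' Converts marker times to half-open sample-index intervals
#' `[round((t - before) * fs), round(t * fs) + round(after * fs))`, clipped to
#' the recording. Indices are 0-based; use `idx + 1` to subset in R.
#'
#' @param markers a `spike_markers` object.
#' @param fs sampling rate (Hz).
#' @param n_samples recording length in samples.
#' @return list of integer vectors `c(start, stop)` (0-based, half-open),
#'   one per marker, in marker order.
#' @export
constraint_windows <- function(markers, fs, n_samples) {
  stopifnot(inherits(markers, "spike_markers"))
  t <- markers$times_s
  if (any(t > n_samples / fs + 1e-9))
    stop("marker time(s) beyond recording end: ",
         paste(format(t[t > n_samples / fs + 1e-9]), collapse = ", "))
  start <- round_half_away((t - markers$window_before_s) * fs)
  stop_ <- round_half_away(t * fs) + round_half_away(markers$window_after_s * fs)
  start <- pmax(start, 0)
  stop_ <- pmin(stop_, n_samples)
  empty <- which(stop_ <= start)
  if (length(empty))
    stop("constraint window empty after clipping for marker(s) at t = ",
         paste(format(t[empty]), collapse = ", "), " s")
  mapply(function(a, b) c(as.integer(a), as.integer(b)),
         start, stop_, SIMPLIFY = FALSE)
}

# flatten windows to 1-based sample indices (for subsetting)
window_indices <- function(windows) {
  unlist(lapply(windows, function(w) seq.int(w[1] + 1L, w[2])), use.names = FALSE)
}

#' Read / write the plain-text marker format
#'
#' One spike-apex time in seconds per line; `#` starts a comment.
#'
#' @param path file path.
#' @param ... passed to [spike_markers()] (window lengths).
#' @return [read_markers()] returns a `spike_markers` object.
#' @export
read_markers <- function(path, ...) {
  if (!file.exists(path)) stop("marker file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  t <- suppressWarnings(as.numeric(ln))
  if (any(is.na(t))) stop("non-numeric marker line(s) in ", path)
  spike_markers(t, ...)
}

#' @rdname read_markers
#' @param markers a `spike_markers` object.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "spike_markers"))
  writeLines(c(sprintf("# spike apex times (s); window -%g/+%g s",
                       markers$window_before_s, markers$window_after_s),
               format(markers$times_s, digits = 15, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
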