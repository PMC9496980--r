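# Interchange formats.
#
# The EEG interchange CSV is plain text: '#'-prefixed metadata lines
# (fs, reference, condition), then a header row "time,<ch>,...", then one row
# per sample with time in seconds. Metadata round-trips exactly; data within
# float formatting.

#' Write an EEG recording to the interchange CSV
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @param digits significant digits for the sample values.
#' @export
write_eeg_csv <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", rec$fs),
               sprintf("# reference=%s", rec$reference),
               sprintf("# condition=%s", rec$condition_tag),
               paste(c("time", rec$channel_names), collapse = ",")), con)
  t <- (seq_len(ncol(rec$data)) - 1) / rec$fs
  m <- cbind(t, t(rec$data))
  utils::write.table(format(m, digits = digits, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", col.names = FALSE, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an EEG recording
#'
#' @param path file path.
#' @param format only `"csv"` (the interchange format) is supported.
#' @return an `eeg_recording`.
#' @export
read_eeg <- function(path, format = "csv") {
  if (!file.exists(path)) stop("EEG file not found: ", path)
  format <- match.arg(format, "csv")
  ln <- readLines(path, warn = FALSE)
  meta_ln <- grep("^#", ln)
  meta <- list(fs = NA_real_, reference = "", condition = "")
  for (l in ln[meta_ln]) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2)
      meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  hdr_i <- setdiff(seq_along(ln), meta_ln)[1]
  hdr <- strsplit(ln[hdr_i], ",", fixed = TRUE)[[1]]
  if (length(hdr) < 3 || tolower(hdr[1]) != "time")
    stop("malformed interchange CSV header at line ", hdr_i,
         ": expected 'time,<ch1>,<ch2>,...'")
  d <- utils::read.csv(text = ln[-c(meta_ln, hdr_i)], header = FALSE)
  if (ncol(d) != length(hdr))
    stop("column count mismatch after line ", hdr_i)
  fs <- suppressWarnings(as.numeric(meta$fs))
  if (!is.finite(fs)) {
    dt <- diff(d[[1]])
    fs <- 1 / stats::median(dt)
  }
  eeg_recording(t(as.matrix(d[, -1, drop = FALSE])), fs,
                channel_names = hdr[-1],
                reference = meta$reference,
                condition_tag = meta$condition)
}

# short deterministic config fingerprint used to tag output files
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}
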