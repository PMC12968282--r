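## Minimal European Data Format (EDF, 16-bit) reader and writer.
##
## Implements the standard fixed-width ASCII header (256 bytes + 256 per
## signal) and little-endian int16 data records with linear
## digital-to-physical scaling. The writer emits one data record holding the
## whole recording and stamps the exact sampling rate and sample count into
## the 44-byte reserved field ("NQ fs=... n=..."), which the reader prefers
## over the quantized record-duration field when present; files from other
## software fall back to nr / duration.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  formatC(s, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write a signal to a 16-bit EDF file
#'
#' Each channel is scaled linearly from its physical range to the full
#' 16-bit digital range, so round-trip error is bounded by
#' (channel range) / 65535. Constant channels are stored with a widened
#' range to keep the scaling well-defined.
#'
#' @param signal An [eeg_signal()].
#' @param path Output path.
#' @param physical_dimension Unit label stored per channel (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path, physical_dimension = "uV") {
  fs <- signal_fs(signal)
  ns <- ncol(signal)
  n <- nrow(signal)
  labels <- names(signal)
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, eos = NULL)

  # 256-byte fixed header
  wchar(edf_pad("0", 8))
  wchar(edf_pad("X X X X", 80))
  wchar(edf_pad("Startdate X X X X", 80))
  wchar(edf_pad("01.01.00", 8))
  wchar(edf_pad("00.00.00", 8))
  wchar(edf_pad(format(256L + 256L * ns), 8))
  wchar(edf_pad(sprintf("NQ fs=%.10g n=%d", fs, n), 44))
  wchar(edf_pad("1", 8)) # one data record
  wchar(edf_num(n / fs, 8)) # record duration, s (quantized; see reserved)
  wchar(edf_pad(format(ns), 4))

  pmin <- vapply(signal, min, numeric(1))
  pmax <- vapply(signal, max, numeric(1))
  flat <- pmax - pmin <= 0
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768L
  dmax <- 32767L

  for (lab in labels) wchar(edf_pad(lab, 16))
  for (i in seq_len(ns)) wchar(edf_pad("", 80)) # transducer
  for (i in seq_len(ns)) wchar(edf_pad(physical_dimension, 8))
  for (i in seq_len(ns)) wchar(edf_num(pmin[i], 8))
  for (i in seq_len(ns)) wchar(edf_num(pmax[i], 8))
  for (i in seq_len(ns)) wchar(edf_pad(format(dmin), 8))
  for (i in seq_len(ns)) wchar(edf_pad(format(dmax), 8))
  for (i in seq_len(ns)) wchar(edf_pad("", 80)) # prefiltering
  for (i in seq_len(ns)) wchar(edf_pad(format(n), 8)) # samples per record
  for (i in seq_len(ns)) wchar(edf_pad("", 32))

  for (i in seq_len(ns)) {
    x <- signal[[i]]
    d <- round((x - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin)
    writeBin(as.integer(d), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' Parses the standard header, applies per-channel digital-to-physical
#' scaling, and concatenates data records. The sampling rate comes from the
#' reserved-field stamp written by [write_edf()] when present, otherwise
#' from samples-per-record / record-duration.
#'
#' @param path EDF file path.
#' @return An [eeg_signal()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rnum <- function(width) {
    v <- suppressWarnings(as.numeric(rchar(width)))
    if (is.na(v)) abort(sprintf("Unparseable numeric field in EDF header of '%s'.", path))
    v
  }
  version <- rchar(8)
  if (version != "0") {
    abort(sprintf("'%s' is not a plain EDF file (version field '%s').", path, version))
  }
  rchar(80); rchar(80); rchar(8); rchar(8)
  header_bytes <- rnum(8)
  reserved <- rchar(44)
  n_records <- rnum(8)
  duration <- rnum(8)
  ns <- as.integer(rnum(4))
  if (ns < 1) abort(sprintf("'%s' declares zero signals.", path))
  if (header_bytes != 256 + 256 * ns) {
    abort(sprintf("Inconsistent EDF header size in '%s'.", path))
  }
  labels <- vapply(seq_len(ns), function(i) rchar(16), character(1))
  for (i in seq_len(ns)) rchar(80)
  for (i in seq_len(ns)) rchar(8)
  pmin <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  pmax <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  for (i in seq_len(ns)) rchar(80)
  nr <- vapply(seq_len(ns), function(i) as.integer(rnum(8)), integer(1))
  for (i in seq_len(ns)) rchar(32)

  chans <- purrr::map(seq_len(ns), function(i) numeric(0))
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = nr[i], size = 2L, signed = TRUE,
        endian = "little")
      if (length(d) < nr[i]) abort(sprintf("Truncated EDF data in '%s'.", path))
      phys <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      chans[[i]] <- c(chans[[i]], phys)
    }
  }

  stamp <- regmatches(
    reserved,
    regexec("NQ fs=([0-9.eE+-]+) n=([0-9]+)", reserved)
  )[[1]]
  if (length(stamp) == 3) {
    fs <- as.numeric(stamp[2])
    n <- as.integer(stamp[3])
    chans <- purrr::map(chans, ~ .x[seq_len(min(n, length(.x)))])
  } else {
    if (duration <= 0) abort(sprintf("EDF '%s' has no usable record duration.", path))
    fs <- nr[1] / duration
  }
  if (length(unique(vapply(chans, length, integer(1)))) != 1) {
    abort(sprintf("Channels of '%s' differ in length; mixed-rate EDF is unsupported.", path))
  }
  eeg_signal(as.data.frame(setNames(chans, make.unique(labels))), fs = fs)
}
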