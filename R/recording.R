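#' Construct a multichannel recording
#'
#' The raw-input container of the pipeline: a samples-by-channels numeric
#' matrix with a common sampling rate.
#'
#' @param data Numeric matrix, samples in rows, channels in columns.
#' @param fs Sampling rate in Hz (common to all channels).
#' @param channel_labels Character vector of channel names; defaults to
#'   `ch01, ch02, ...`.
#' @param start_time Recording start offset in seconds (default 0).
#' @param meta Optional list of free-form metadata (hardware filters,
#'   synthesis ground truth, ...), carried through unchanged.
#' @return An object of class `mc_recording`.
#' @export
mc_recording <- function(data, fs, channel_labels = NULL, start_time = 0,
                         meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2) abort("A recording needs at least 2 channels.")
  if (anyNA(data) || any(!is.finite(data))) {
    abort("Recording contains NA or non-finite samples; reject or impute before loading.")
  }
  if (fs <= 0) abort("`fs` must be positive.")
  channel_labels <- channel_labels %||% sprintf("ch%02d", seq_len(ncol(data)))
  if (length(channel_labels) != ncol(data)) {
    abort("`channel_labels` length must match the number of channels.")
  }
  colnames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 start_time = start_time, meta = meta),
            class = "mc_recording")
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf("<mc_recording> %d channels x %d samples at %g Hz (%.1f s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
as_tibble.mc_recording <- function(x, ...) {
  tb <- as_tibble(x$data)
  tb$time_s <- x$start_time + (seq_len(nrow(x$data)) - 1) / x$fs
  tidyr::pivot_longer(tb, -"time_s", names_to = "channel", values_to = "value")
}

#' Duration of a recording in seconds
#' @param rec An `mc_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$fs

sniff_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Load a multichannel recording from disk
#'
#' Supports European Data Format (EDF) files and plain delimited numeric text
#' (one column per channel, one row per sample; tab, comma or whitespace
#' separated, with an optional header row of channel labels). For text input
#' the sampling rate must come from `fs` or from a JSON sidecar file
#' (`<path>.json` or as named in `sidecar`) with at least a `fs` field;
#' the sidecar may also carry `channel_labels`, `start_time` and `meta`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @param fs Sampling rate in Hz for text input (overrides the sidecar).
#' @param sidecar Optional path to the JSON sidecar.
#' @return An [mc_recording()].
#' @export
load_recording <- function(path, format = c("auto", "edf", "text"),
                           fs = NULL, sidecar = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  if (format == "edf") return(read_edf(path))

  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) abort(sprintf("Empty file: %s", path))
  sep <- sniff_sep(first)
  tokens <- strsplit(trimws(first), if (sep == "") "\\s+" else sep)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(tokens)))
  df <- read.table(path, header = has_header, sep = sep)
  if (nrow(df) == 0 || ncol(df) == 0) abort(sprintf("Empty file: %s", path))
  if (!all(vapply(df, is.numeric, TRUE))) {
    abort("Text recording contains non-numeric columns.")
  }

  meta <- list(); labels <- if (has_header) names(df) else NULL; start <- 0
  sc <- sidecar %||% paste0(path, ".json")
  if (file.exists(sc)) {
    info <- jsonlite::read_json(sc, simplifyVector = TRUE)
    fs <- fs %||% info$fs
    labels <- labels %||% info$channel_labels
    start <- info$start_time %||% 0
    meta <- info$meta %||% list()
  }
  if (is.null(fs)) {
    abort("Sampling rate missing for text input: pass `fs` or provide a JSON sidecar.")
  }
  mc_recording(as.matrix(df), fs = fs, channel_labels = labels,
               start_time = start, meta = meta)
}

#' Write a recording as delimited text (+ JSON sidecar)
#'
#' @param rec An [mc_recording()].
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @param sidecar Write the JSON sidecar too? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_recording_text <- function(rec, path, sidecar = TRUE) {
  write.table(rec$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(fs = rec$fs, channel_labels = rec$channel_labels,
           start_time = rec$start_time, meta = rec$meta),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# --- Minimal EDF (European Data Format) reader/writer -----------------------
# EDF has a 256-byte fixed ASCII header, 256 bytes of per-signal ASCII header
# fields, and data records of little-endian int16 samples. No R package for
# EDF is declared here, so the (simple, fully specified) format is handled
# directly.

edf_field <- function(con, nchars) trimws(readChar(con, nchars, useBytes = TRUE))

read_edf <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) abort(sprintf("Not a valid EDF file (too short): %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                      # version
  edf_field(con, 80); edf_field(con, 80) # patient / recording id
  edf_field(con, 8); edf_field(con, 8)   # start date / time
  edf_field(con, 8)                      # header bytes
  edf_field(con, 44)                     # reserved
  n_rec <- as.integer(edf_field(con, 8))
  dur_rec <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) abort("Malformed EDF header: bad signal count.")
  rd <- function(nc) vapply(seq_len(ns), function(i) edf_field(con, nc), "")
  labels <- rd(16); rd(80); rd(8)        # label, transducer, physical dim
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin_ <- as.numeric(rd(8)); dmax_ <- as.numeric(rd(8))
  prefilter <- rd(80)
  spr <- as.integer(rd(8)); rd(32)       # samples per record, reserved

  fs_per <- spr / dur_rec
  if (length(unique(fs_per)) > 1) {
    bad <- labels[fs_per != fs_per[1]]
    abort(sprintf(
      "EDF has mixed per-channel sampling rates; offending channels: %s",
      paste(bad, collapse = ", ")))
  }
  total <- sum(spr) * n_rec
  raw <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw) < total) abort("Truncated EDF data section.")
  sig <- matrix(0, nrow = spr[1] * n_rec, ncol = ns)
  off <- 0L
  starts <- c(0L, cumsum(spr))
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * sum(spr)
    for (s in seq_len(ns)) {
      idx <- base + starts[s] + seq_len(spr[s])
      sig[(r - 1L) * spr[s] + seq_len(spr[s]), s] <- raw[idx]
    }
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (s in seq_len(ns)) sig[, s] <- (sig[, s] - dmin_[s]) * gain[s] + pmin_[s]
  mc_recording(sig, fs = fs_per[1], channel_labels = labels,
               meta = list(prefilter = prefilter[1], source = "edf"))
}

pad_field <- function(x, n) {
  s <- substr(format(x), 1, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a recording as an EDF file
#'
#' Minimal EDF writer (single record duration of 1 s, physical range set to
#' the data range, 16-bit samples). Intended for interchange and round-trip
#' testing, not for clinical archiving.
#'
#' @param rec An [mc_recording()]; its length is truncated to a whole number
#'   of 1-second records.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate.")
  n_rec <- floor(nrow(rec$data) / fs)
  if (n_rec < 1) abort("Recording shorter than one 1-second EDF record.")
  ns <- ncol(rec$data)
  dat <- rec$data[seq_len(n_rec * fs), , drop = FALSE]
  pmin_ <- apply(dat, 2, min); pmax_ <- apply(dat, 2, max)
  flat <- pmax_ == pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dig <- sapply(seq_len(ns), function(s) {
    round((dat[, s] - pmin_[s]) / (pmax_[s] - pmin_[s]) * 65534 - 32767)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeChar(pad_field(x, n), con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (1 + ns), 8); wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (s in seq_len(ns)) wr(rec$channel_labels[s], 16)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr("uV", 8)
  for (s in seq_len(ns)) wr(signif(pmin_[s], 7), 8)
  for (s in seq_len(ns)) wr(signif(pmax_[s], 7), 8)
  for (s in seq_len(ns)) wr(-32767, 8)
  for (s in seq_len(ns)) wr(32767, 8)
  for (s in seq_len(ns)) wr("", 80)
  for (s in seq_len(ns)) wr(fs, 8)
  for (s in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      writeBin(as.integer(dig[(r - 1) * fs + seq_len(fs), s]),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
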