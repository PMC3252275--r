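#' Sliding analysis windows over a recording
#'
#' Splits a recording into fixed-length windows advancing by
#' `length_s - overlap_s` seconds; a trailing partial window is discarded.
#' With the defaults (150 s windows, 100 s overlap) a 150 s record at 200 Hz
#' yields a single window of 30000 samples, and 38400 samples at 256 Hz.
#'
#' @param rec An [mc_recording()].
#' @param length_s Window length in seconds (default 150).
#' @param overlap_s Overlap between consecutive windows in seconds
#'   (default 100); must satisfy `0 <= overlap_s < length_s`.
#' @return Tibble with `window_id` (0-based), `start_s`, `start_sample`,
#'   `end_sample` (1-based, inclusive).
#' @export
make_windows <- function(rec, length_s = 150, overlap_s = 100) {
  stopifnot(inherits(rec, "mc_recording"))
  if (!(overlap_s >= 0 && overlap_s < length_s)) {
    abort("Require 0 <= overlap_s < length_s.")
  }
  n <- nrow(rec$data)
  len <- round(length_s * rec$fs)
  step <- round((length_s - overlap_s) * rec$fs)
  if (n < len) {
    abort(sprintf("Recording (%d samples) shorter than one window (%d samples).",
                  n, len))
  }
  n_win <- floor((n - len) / step) + 1
  id <- seq_len(n_win) - 1L
  tibble(window_id = id,
         start_s = rec$start_time + id * (length_s - overlap_s),
         start_sample = id * step + 1L,
         end_sample = id * step + len)
}

# All unordered channel pairs as a two-column matrix of indices.
channel_pairs <- function(n_ch) {
  idx <- utils::combn(n_ch, 2)
  t(idx)
}

#' Pooled phase-lock intervals per window and scale
#'
#' For every analysis window and wavelet scale, computes phase-lock intervals
#' for all unordered channel pairs and pools the durations (intervals are cut
#' at window boundaries; boundary-truncated intervals are kept). This is the
#' distribution-building step of the sliding-window analysis.
#'
#' @param rec An [mc_recording()].
#' @param windows Window table from [make_windows()]; defaults to the full
#'   standard windowing of `rec`.
#' @param scales Integer wavelet scales (default `2:4`).
#' @param lock_threshold Phase-lock threshold in radians (default `pi/4`).
#' @param min_coherence Coherence gate (default 0.5).
#' @param avg_window,edge_trim Passed to [phase_pair_series()]; `NULL` uses
#'   the scale-covariant defaults.
#' @param channels Optional subset of channel indices or labels.
#' @return Tibble `(pair_id, scale, window_id, duration_samples,
#'   duration_seconds)` with one row per interval, plus attributes `fs` and
#'   `bands` (the scale-to-frequency map).
#' @export
window_pli <- function(rec, windows = NULL, scales = 2:4,
                       lock_threshold = pi / 4, min_coherence = 0.5,
                       avg_window = NULL, edge_trim = NULL, channels = NULL) {
  stopifnot(inherits(rec, "mc_recording"))
  windows <- windows %||% make_windows(rec)
  dat <- rec$data
  if (!is.null(channels)) dat <- dat[, channels, drop = FALSE]
  n_ch <- ncol(dat)
  if (n_ch < 2) abort("Need at least 2 channels.")
  labels <- colnames(dat)
  pairs <- channel_pairs(n_ch)

  out <- purrr::pmap(windows, function(window_id, start_s, start_sample, end_sample) {
    seg <- dat[start_sample:end_sample, , drop = FALSE]
    hw <- lapply(seq_len(n_ch), function(ch) {
      hilbert_wavelet_transform(seg[, ch], rec$fs, scales)
    })
    purrr::map_dfr(scales, function(j) {
      purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
        i <- pairs[p, 1]; k <- pairs[p, 2]
        pps <- phase_pair_series(hw[[i]], hw[[k]], scale = j,
                                 avg_window = avg_window,
                                 min_coherence = min_coherence,
                                 edge_trim = edge_trim)
        extract_pli(pps, lock_threshold = lock_threshold,
                    pair_id = paste(labels[i], labels[k], sep = "-"),
                    window_id = window_id)
      })
    })
  })
  res <- dplyr::bind_rows(out)
  attr(res, "fs") <- rec$fs
  attr(res, "bands") <- tibble(
    scale = scales,
    f_low_hz = vapply(scales, function(j) scale_band(j, rec$fs)[1], 0),
    f_high_hz = vapply(scales, function(j) scale_band(j, rec$fs)[2], 0))
  res
}

#' Timecourse of the deviation from the initial power law
#'
#' The end-to-end sliding-window analysis: pooled PLI distributions per
#' window and scale, a power law fitted to the reference window (window 0 by
#' default, frozen thereafter), and the signed deviation statistic of every
#' window against that reference. On recordings spanning a seizure the
#' deviation rises to positive values in windows covering the event and
#' relaxes afterwards.
#'
#' @inheritParams window_pli
#' @param length_s,overlap_s Windowing (defaults 150 s / 100 s).
#' @param reference_window Window id whose fit becomes the frozen reference
#'   (default 0, the first window).
#' @param min_tail Minimum tail points required of the reference fit.
#' @return Tibble of class `delta_timecourse` with columns `window_id`,
#'   `start_s`, `scale`, `delta`, `n`; the per-scale reference fits are in
#'   `attr(, "reference")` and the PLI table in `attr(, "pli")`.
#' @export
delta_timecourse <- function(rec, scales = 2:4, length_s = 150,
                             overlap_s = 100, lock_threshold = pi / 4,
                             min_coherence = 0.5, avg_window = NULL,
                             edge_trim = NULL, reference_window = 0,
                             min_tail = 10) {
  windows <- make_windows(rec, length_s, overlap_s)
  pli <- window_pli(rec, windows, scales = scales,
                    lock_threshold = lock_threshold,
                    min_coherence = min_coherence,
                    avg_window = avg_window, edge_trim = edge_trim)
  out <- delta_from_pli(pli, windows = windows,
                        reference_window = reference_window,
                        min_tail = min_tail)
  attr(out, "pli") <- pli
  out
}

#' Deviation timecourse from a precomputed PLI table
#'
#' @param pli PLI tibble from [window_pli()] (or read back from TSV).
#' @param windows Optional window table supplying `start_s`; omitted columns
#'   fall back to `window_id` order.
#' @param reference_window Window id of the frozen reference fit.
#' @param min_tail Minimum tail points for the reference fit.
#' @return A `delta_timecourse` tibble (see [delta_timecourse()]).
#' @export
delta_from_pli <- function(pli, windows = NULL, reference_window = 0,
                           min_tail = 10) {
  stopifnot(all(c("scale", "window_id", "duration_seconds") %in% names(pli)))
  scales <- sort(unique(pli$scale))
  wins <- sort(unique(pli$window_id))
  refs <- lapply(scales, function(j) {
    ref_durs <- pli$duration_seconds[pli$scale == j &
                                       pli$window_id == reference_window]
    fit <- tryCatch(
      fit_power_law(ref_durs, min_tail = min_tail, compare = character()),
      error = function(e) {
        abort(sprintf(
          "Reference fit failed for window %d, scale %d: %s",
          reference_window, j, conditionMessage(e)))
      })
    fit
  })
  names(refs) <- as.character(scales)

  out <- purrr::map_dfr(scales, function(j) {
    ref <- refs[[as.character(j)]]
    purrr::map_dfr(wins, function(w) {
      durs <- pli$duration_seconds[pli$scale == j & pli$window_id == w]
      tl_n <- sum(durs >= ref$xmin)
      d <- if (tl_n >= 1) compute_delta(durs, ref)$delta else NA_real_
      tibble(window_id = w, scale = j, delta = d, n = tl_n)
    })
  })
  if (!is.null(windows)) {
    out <- dplyr::left_join(out,
                            windows[, c("window_id", "start_s")],
                            by = "window_id")
    out <- out[, c("window_id", "start_s", "scale", "delta", "n")]
  }
  out <- dplyr::arrange(out, .data$scale, .data$window_id)
  structure(out, class = c("delta_timecourse", class(out)),
            reference = refs, reference_window = reference_window)
}

#' Write a delta timecourse as TSV
#' @param dtc A `delta_timecourse`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_delta_tsv <- function(dtc, path) {
  write.table(as.data.frame(dtc), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
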