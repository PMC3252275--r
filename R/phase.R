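#' Scale-resolved phase relation between two signals
#'
#' Forms the instantaneous complex phase vector
#' `C(t) = W_j(x) W_j*(y) / |W_j(x) W_j*(y)|` from the analytic wavelet
#' coefficients of two signals at one scale, smooths it with a centered
#' sliding mean over `avg_window` samples, and derives the local mean phase
#' difference `arg<C>` together with a coherence estimate `|<C>|^2`. Samples
#' whose coherence exceeds `min_coherence` (and which are clear of the record
#' edges) are flagged significant; phase-lock intervals are read off this
#' series by [extract_pli()].
#'
#' Samples where either coefficient vanishes exactly (for instance a constant
#' signal) contribute a zero vector to the mean, so fully degenerate stretches
#' get coherence 0 and are excluded rather than producing 0/0.
#'
#' @param wx,wy `hw_coefs` objects on the same time grid and sampling rate.
#' @param scale Scale index present in both transforms.
#' @param avg_window Smoothing window in samples; default `2 * 2^scale`
#'   (two periods of the band's slowest component).
#' @param min_coherence Significance gate on `|<C>|^2`; default 0.5.
#' @param edge_trim Samples at each record edge marked insignificant
#'   (boundary transients of the undecimated filter); default `2^(scale + 2)`.
#' @return A tibble of class `phase_pair_series` with columns `t` (sample
#'   index), `c` (unit-modulus complex phase vector), `c_smooth`, `dphi`
#'   (radians in (-pi, pi]), `coherence` and `sig`. Scale, sampling rate and
#'   the parameters are carried as attributes.
#' @export
phase_pair_series <- function(wx, wy, scale,
                              avg_window = NULL,
                              min_coherence = 0.5,
                              edge_trim = NULL) {
  stopifnot(inherits(wx, "hw_coefs"), inherits(wy, "hw_coefs"))
  if (wx$n != wy$n || wx$fs != wy$fs) {
    abort("`wx` and `wy` must share the same time grid and sampling rate.")
  }
  key <- as.character(as.integer(scale))
  if (is.null(wx$coefs[[key]]) || is.null(wy$coefs[[key]])) {
    abort(sprintf("Scale %s not present in both transforms.", key))
  }
  scale <- as.integer(scale)
  avg_window <- as.integer(avg_window %||% (2L * 2L^scale))
  if (avg_window < 1) abort("`avg_window` must be >= 1.")
  edge_trim <- as.integer(edge_trim %||% 2L^(scale + 2L))

  z <- wx$coefs[[key]] * Conj(wy$coefs[[key]])
  m <- Mod(z)
  cvec <- complex(real = numeric(wx$n), imaginary = numeric(wx$n))
  ok <- m > 0
  cvec[ok] <- z[ok] / m[ok]
  csm <- sliding_mean_complex(cvec, avg_window)
  coh <- Mod(csm)^2
  coh[is.na(coh)] <- 0
  coh <- pmin(coh, 1)
  dphi <- Arg(csm)
  dphi[coh == 0] <- NA_real_

  n <- wx$n
  edge <- rep(FALSE, n)
  if (edge_trim > 0) {
    lo <- seq_len(min(edge_trim, n))
    edge[lo] <- TRUE
    edge[n - lo + 1L] <- TRUE
  }
  sig <- coh > min_coherence & !edge & !is.na(dphi)

  out <- tibble(
    t = seq_len(n), c = cvec, c_smooth = csm,
    dphi = dphi, coherence = coh, sig = sig
  )
  structure(out,
            class = c("phase_pair_series", class(out)),
            scale = scale, fs = wx$fs, avg_window = avg_window,
            min_coherence = min_coherence, edge_trim = edge_trim)
}

#' Extract phase-lock intervals from a phase pair series
#'
#' A phase-lock interval (PLI) is a maximal run of consecutive samples where
#' the smoothed phase difference satisfies `|dphi| < lock_threshold` and the
#' coherence gate passes. Durations are counted in samples and converted to
#' seconds with the series' sampling rate.
#'
#' @param pps A [phase_pair_series()] result.
#' @param lock_threshold Phase-locking threshold in radians, in `(0, pi)`;
#'   default `pi / 4`.
#' @param pair_id,window_id Optional provenance labels stored with every
#'   interval.
#' @return A tibble with columns `pair_id`, `scale`, `window_id`,
#'   `duration_samples`, `duration_seconds`. Zero rows is a valid result.
#' @export
extract_pli <- function(pps, lock_threshold = pi / 4,
                        pair_id = NA_character_, window_id = NA_integer_) {
  stopifnot(inherits(pps, "phase_pair_series"))
  if (!(lock_threshold > 0 && lock_threshold < pi)) {
    abort("`lock_threshold` must lie in (0, pi).")
  }
  locked <- pps$sig & !is.na(pps$dphi) & abs(pps$dphi) < lock_threshold
  durs <- run_lengths_true(locked)
  fs <- attr(pps, "fs")
  tibble(
    pair_id = rep(pair_id, length(durs)),
    scale = rep(attr(pps, "scale"), length(durs)),
    window_id = rep(as.integer(window_id), length(durs)),
    duration_samples = durs,
    duration_seconds = durs / fs
  )
}

#' Write a PLI table to TSV
#'
#' @param pli Tibble as returned by [extract_pli()] or [window_pli()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pli_tsv <- function(pli, path) {
  write.table(pli, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLI table written by [write_pli_tsv()]
#' @param path File path.
#' @return A tibble.
#' @export
read_pli_tsv <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}
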