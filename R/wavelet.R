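#' Dyadic frequency band of a wavelet scale
#'
#' Scale `j` of the analytic dyadic decomposition covers the octave
#' `[fs / 2^(j+1), fs / 2^j]`. At 200 Hz sampling, scales 2, 3 and 4 thus
#' correspond to 25--50 Hz, 12.5--25 Hz and 6.25--12.5 Hz.
#'
#' @param scale Integer scale index `j >= 1`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector `c(low, high)` in Hz.
#' @export
#' @examples
#' scale_band(2, 200) # 25 50
scale_band <- function(scale, fs) {
  stopifnot(scale >= 1, fs > 0)
  c(fs / 2^(scale + 1), fs / 2^scale)
}

# Meyer auxiliary polynomial: smooth monotone map [0,1] -> [0,1].
meyer_nu <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# Amplitude response of the analytic Meyer-type band filter for one scale,
# evaluated at (non-negative) frequencies f. The response rises over
# [2/3, 4/3] * f_lo as sin(pi/2 nu(.)) and falls over [2/3, 4/3] * f_hi as
# cos(pi/2 nu(.)); adjacent scales are in power quadrature so that the squared
# responses tile the axis (a partition of unity in energy).
hw_response <- function(f, scale, fs) {
  band <- scale_band(scale, fs)
  f_lo <- band[1]
  f_hi <- band[2]
  amp <- numeric(length(f))
  rise <- f > 2 / 3 * f_lo & f < 4 / 3 * f_lo
  flat <- f >= 4 / 3 * f_lo & f <= 2 / 3 * f_hi
  fall <- f > 2 / 3 * f_hi & f < 4 / 3 * f_hi
  amp[rise] <- sin(pi / 2 * meyer_nu((3 * f[rise] / (2 * f_lo) - 1)))
  amp[flat] <- 1
  amp[fall] <- cos(pi / 2 * meyer_nu((3 * f[fall] / (2 * f_hi) - 1)))
  # the top scale's falling edge may extend past Nyquist; keep the passband
  # flat there instead of rolling off into unobservable frequencies
  if (4 / 3 * f_hi > fs / 2) {
    amp[f > 2 / 3 * f_hi & f <= fs / 2] <- 1
  }
  amp[f == 0] <- 0
  amp
}

#' Minimum record length for a wavelet scale
#'
#' @param scale Largest scale index requested.
#' @return Minimum number of samples, `2^(scale + 2)`.
#' @export
hw_min_length <- function(scale) 2^(scale + 2)

#' Analytic (Hilbert-pair) dyadic wavelet transform
#'
#' Decomposes a real signal into complex, approximately analytic coefficients
#' on dyadic frequency bands, one series per requested scale, on the original
#' time grid (undecimated, shift invariant). The filter bank is a Meyer-type
#' construction applied in the frequency domain: each scale has a smooth
#' raised-cosine response confined to its octave `[fs/2^(j+1), fs/2^j]`
#' (transition bands of relative width 1/3 on each edge), with negative
#' frequencies suppressed so that the coefficient argument is an instantaneous
#' phase. The same fixed filter family is used everywhere in the package.
#'
#' @param x Real-valued numeric vector.
#' @param fs Sampling rate in Hz.
#' @param scales Integer vector of scale indices (`j >= 1`).
#' @return An object of class `hw_coefs`: a list with elements `coefs` (named
#'   list of complex vectors, one per scale), `fs`, `scales` and `n`.
#' @export
#' @examples
#' x <- sin(2 * pi * 30 * seq(0, 1, by = 1 / 200))
#' w <- hilbert_wavelet_transform(x, fs = 200, scales = 2:4)
#' sapply(w$coefs, function(z) mean(Mod(z)^2))
hilbert_wavelet_transform <- function(x, fs, scales) {
  if (!is.numeric(x)) abort("`x` must be a numeric vector.")
  if (anyNA(x) || any(!is.finite(x))) abort("`x` must be finite (no NA/Inf).")
  scales <- as.integer(scales)
  if (length(scales) < 1 || any(scales < 1)) abort("`scales` must be integers >= 1.")
  if (fs <= 0) abort("`fs` must be positive.")
  n <- length(x)
  need <- hw_min_length(max(scales))
  if (n < need) {
    abort(sprintf(
      "Signal too short for scale %d: %d samples given, at least %d required.",
      max(scales), n, need
    ))
  }
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- (seq_len(nfft) - 1) / nfft * fs
  pos <- f <= fs / 2          # analytic: keep non-negative frequencies only
  coefs <- lapply(scales, function(j) {
    H <- numeric(nfft)
    H[pos] <- 2 * hw_response(f[pos], j, fs)
    w <- stats::fft(X * H, inverse = TRUE) / nfft
    w[seq_len(n)]
  })
  structure(
    list(coefs = setNames(coefs, as.character(scales)),
         fs = fs, scales = scales, n = n),
    class = "hw_coefs"
  )
}

#' @export
print.hw_coefs <- function(x, ...) {
  cat(sprintf("<hw_coefs> %d samples at %g Hz, scales %s\n",
              x$n, x$fs, paste(x$scales, collapse = ", ")))
  invisible(x)
}
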