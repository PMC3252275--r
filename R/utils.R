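# Internal helpers shared across modules.

# Lengths of maximal runs of TRUE in a logical vector (NA counts as FALSE).
run_lengths_true <- function(x) {
  x <- !is.na(x) & x
  r <- rle(x)
  as.integer(r$lengths[r$values])
}

# Centered sliding mean of a complex series over `w` samples.
# Positions where the full window does not fit are NA (handled by callers
# through the edge mask).
sliding_mean_complex <- function(z, w) {
  if (w == 1L) return(z)
  k <- rep(1 / w, w)
  re <- stats::filter(Re(z), k, sides = 2)
  im <- stats::filter(Im(z), k, sides = 2)
  complex(real = as.numeric(re), imaginary = as.numeric(im))
}

# Right-continuous empirical complementary CDF, P(X >= x), evaluated at the
# (sorted ascending) sample points themselves. Ties share the value obtained
# by counting all observations >= the tied value.
ccdf_at_sorted <- function(x_sorted) {
  n <- length(x_sorted)
  # number of observations >= x_(i): n - (first index of the tie group) + 1
  first_idx <- match(x_sorted, x_sorted)
  (n - first_idx + 1) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
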