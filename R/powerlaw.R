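#' Empirical complementary cumulative distribution
#'
#' Right-continuous survival function `P(X >= x)` of a positive sample,
#' evaluated at its unique values.
#'
#' @param x Positive numeric vector.
#' @return A tibble with columns `value` (sorted ascending) and `ccdf`;
#'   `ccdf` equals 1 at the smallest value and is non-increasing.
#' @export
empirical_ccdf <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1, all(x > 0))
  tb <- table(sort(x))
  vals <- as.numeric(names(tb))
  cnt <- as.integer(tb)
  tibble(value = vals, ccdf = rev(cumsum(rev(cnt))) / length(x))
}

# Pareto (continuous power law) helpers. `alpha` is the density exponent,
# p(x) = (alpha - 1)/xmin * (x/xmin)^(-alpha), x >= xmin; the survival
# function is (x/xmin)^(-(alpha - 1)).
ppareto_sf <- function(x, alpha, xmin) (x / xmin)^(-(alpha - 1))

qpareto <- function(p, alpha, xmin) xmin * (1 - p)^(-1 / (alpha - 1))

rpareto <- function(n, alpha, xmin) qpareto(runif(n), alpha, xmin)

# KS distance between the empirical CDF of a sorted tail and the fitted
# Pareto CDF (sup over both step sides).
pl_ks <- function(tail_sorted, alpha, xmin) {
  n <- length(tail_sorted)
  Fth <- 1 - ppareto_sf(tail_sorted, alpha, xmin)
  i <- seq_len(n)
  max(pmax(abs(i / n - Fth), abs((i - 1) / n - Fth)))
}

pl_alpha_mle <- function(tail_vals, xmin) {
  s <- sum(log(tail_vals / xmin))
  if (s <= 0) return(NA_real_)
  1 + length(tail_vals) / s
}

#' Fit a power law to positive durations
#'
#' Continuous maximum-likelihood fit of a Pareto tail with the lower cutoff
#' `xmin` selected by minimizing the Kolmogorov--Smirnov distance between the
#' empirical tail and the fitted model, in the manner standard for power-law
#' inference on empirical data. Candidate cutoffs are the unique sample values
#' restricted to the smallest 90% (so the tail keeps at least `min_tail`
#' points); when there are many unique values a quantile-spaced subset of at
#' most `max_candidates` is scanned. Alternative tail models (exponential and
#' lognormal, both conditioned on `x >= xmin`) are compared through normalized
#' (Vuong-type) log-likelihood ratios.
#'
#' @param x Positive numeric vector of durations (seconds or samples); also
#'   accepts a data frame with a `duration_seconds` column, so PLI tables
#'   pipe in directly.
#' @param xmin Optional fixed lower cutoff; when supplied the KS scan is
#'   skipped.
#' @param min_n Minimum sample size (default 10).
#' @param min_tail Minimum number of points that must remain above any
#'   candidate cutoff (default 10).
#' @param max_candidates Cap on the number of scanned cutoffs (default 150).
#' @param compare Character vector of alternative tail models to score;
#'   any of `"exponential"`, `"lognormal"`. Use `character()` to skip.
#' @return An object of class `pl_fit`: list with `alpha`, `xmin`, `ks`,
#'   `n_tail`, `n`, `sd_alpha`, `loglik`, `compare` (tibble of alternatives),
#'   `gof_p` (`NA` until [ks_gof()] is run) and the data in `x`.
#' @seealso [ks_gof()], [compute_delta()], [ccdf_slope()]
#' @export
#' @examples
#' set.seed(1)
#' x <- 1 * (1 - runif(2000))^(-1 / 1.5) # Pareto, density exponent 2.5
#' fit <- fit_power_law(x)
#' glance(fit)
fit_power_law <- function(x, xmin = NULL, min_n = 10, min_tail = 10,
                          max_candidates = 150,
                          compare = c("exponential", "lognormal")) {
  if (is.data.frame(x)) {
    if (!"duration_seconds" %in% names(x)) {
      abort("Data-frame input must have a `duration_seconds` column.")
    }
    x <- x$duration_seconds
  }
  x <- as.numeric(x)
  if (anyNA(x) || any(x <= 0)) abort("Durations must be positive and non-missing.")
  n <- length(x)
  if (n < min_n) {
    abort(sprintf("Too few durations: %d given, %d required.", n, min_n))
  }
  xs <- sort(x)

  if (is.null(xmin)) {
    u <- unique(xs)
    cand <- u[u <= quantile(u, 0.9, type = 1)]
    # keep >= min_tail points above the cutoff
    cand <- cand[vapply(cand, function(m) sum(xs >= m), 0L) >= min_tail]
    if (length(cand) == 0) {
      abort(sprintf("No candidate xmin leaves %d tail samples (n_tail too small).",
                    min_tail))
    }
    if (length(cand) > max_candidates) {
      idx <- unique(round(seq(1, length(cand), length.out = max_candidates)))
      cand <- cand[idx]
    }
    scan <- vapply(cand, function(m) {
      tl <- xs[xs >= m]
      a <- pl_alpha_mle(tl, m)
      if (is.na(a) || a <= 1) return(c(NA_real_, NA_real_))
      c(a, pl_ks(tl, a, m))
    }, numeric(2))
    ok <- !is.na(scan[2, ])
    if (!any(ok)) abort("Power-law fit failed: no valid xmin candidate.")
    best <- which(ok)[which.min(scan[2, ok])]
    xmin <- cand[best]
  }

  tl <- xs[xs >= xmin]
  n_tail <- length(tl)
  if (n_tail < min_tail) {
    msg <- sprintf("Too few tail samples above xmin = %g: n_tail = %d (< %d).",
                   xmin, n_tail, min_tail)
    cnd <- rlang::error_cnd(class = "plicrit_tail_error", message = msg,
                            n_tail = n_tail)
    rlang::cnd_signal(cnd)
  }
  alpha <- pl_alpha_mle(tl, xmin)
  if (is.na(alpha) || alpha <= 1) abort("Degenerate tail: MLE exponent <= 1.")
  ks <- pl_ks(tl, alpha, xmin)
  loglik <- n_tail * log(alpha - 1) - n_tail * log(xmin) -
    alpha * sum(log(tl / xmin))

  cmp <- pl_compare(tl, alpha, xmin, compare)

  structure(
    list(alpha = alpha, xmin = xmin, ks = ks, n_tail = n_tail, n = n,
         sd_alpha = (alpha - 1) / sqrt(n_tail), loglik = loglik,
         compare = cmp, gof_p = NA_real_, x = x,
         settings = list(min_tail = min_tail, max_candidates = max_candidates,
                         compare = compare)),
    class = "pl_fit"
  )
}

# Normalized log-likelihood-ratio comparison of the fitted power-law tail
# against alternative models conditioned on x >= xmin. Positive `lr` favors
# the power law; `p` is the two-sided Vuong p-value for the ratio being
# distinguishable from zero.
pl_compare <- function(tl, alpha, xmin, compare) {
  out <- lapply(compare, function(alt) {
    n <- length(tl)
    l_pl <- log(alpha - 1) - log(xmin) - alpha * log(tl / xmin)
    l_alt <- switch(
      alt,
      exponential = {
        rate <- 1 / max(mean(tl) - xmin, .Machine$double.eps)
        log(rate) - rate * (tl - xmin)
      },
      lognormal = {
        lt <- log(tl)
        fn <- function(p) {
          mu <- p[1]; sg <- exp(p[2])
          tailp <- stats::plnorm(xmin, mu, sg, lower.tail = FALSE)
          if (tailp <= 0) return(1e10)
          -sum(stats::dlnorm(tl, mu, sg, log = TRUE) - log(tailp))
        }
        opt <- optim(c(mean(lt), log(sd(lt) + 1e-6)), fn)
        mu <- opt$par[1]; sg <- exp(opt$par[2])
        stats::dlnorm(tl, mu, sg, log = TRUE) -
          stats::plnorm(xmin, mu, sg, lower.tail = FALSE, log.p = TRUE)
      },
      abort(sprintf("Unknown alternative '%s'.", alt))
    )
    d <- l_pl - l_alt
    lr <- sum(d)
    sdd <- sd(d)
    z <- if (sdd > 0) lr / (sdd * sqrt(n)) else NA_real_
    tibble(alternative = alt, lr = lr, z = z,
           p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)))
  })
  dplyr::bind_rows(out)
}

#' @export
print.pl_fit <- function(x, ...) {
  cat(sprintf(
    "<pl_fit> alpha = %.3f (sd %.3f), xmin = %g, KS = %.4f, tail n = %d / %d\n",
    x$alpha, x$sd_alpha, x$xmin, x$ks, x$n_tail, x$n))
  if (!is.na(x$gof_p)) cat(sprintf("  bootstrap GoF p = %.3f\n", x$gof_p))
  if (nrow(x$compare)) {
    for (i in seq_len(nrow(x$compare))) {
      cat(sprintf("  vs %-11s LR = %8.2f  (p = %.3f)\n",
                  x$compare$alternative[i], x$compare$lr[i], x$compare$p[i]))
    }
  }
  invisible(x)
}

#' @export
tidy.pl_fit <- function(x, ...) {
  tibble(term = c("alpha", "xmin"),
         estimate = c(x$alpha, x$xmin),
         std.error = c(x$sd_alpha, NA_real_))
}

#' @export
glance.pl_fit <- function(x, ...) {
  cmp <- x$compare
  grab <- function(alt, col) {
    v <- cmp[[col]][cmp$alternative == alt]
    if (length(v)) v else NA_real_
  }
  tibble(alpha = x$alpha, xmin = x$xmin, ks = x$ks,
         n_tail = x$n_tail, n = x$n, logLik = x$loglik, gof_p = x$gof_p,
         lr_exponential = grab("exponential", "lr"),
         p_exponential = grab("exponential", "p"),
         lr_lognormal = grab("lognormal", "lr"),
         p_lognormal = grab("lognormal", "p"))
}

#' Semi-parametric bootstrap goodness-of-fit for a power-law fit
#'
#' Generates `n_boot` synthetic samples of the same size as the data, drawing
#' each observation from the fitted Pareto tail with probability
#' `n_tail / n` and otherwise resampling the below-cutoff body, refits each
#' sample (including the cutoff scan), and reports the fraction of synthetic
#' KS distances at least as large as the observed one. Small p-values reject
#' the power-law hypothesis.
#'
#' @param fit A [fit_power_law()] object.
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @return The fit, with `gof_p` filled in and the bootstrap KS distances in
#'   `boot_ks`.
#' @export
ks_gof <- function(fit, n_boot = 200) {
  stopifnot(inherits(fit, "pl_fit"))
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  x <- fit$x
  n <- fit$n
  body <- x[x < fit$xmin]
  p_tail <- fit$n_tail / n
  ks_b <- vapply(seq_len(n_boot), function(b) {
    from_tail <- runif(n) < p_tail
    synth <- numeric(n)
    synth[from_tail] <- rpareto(sum(from_tail), fit$alpha, fit$xmin)
    n_body <- sum(!from_tail)
    if (n_body > 0) {
      synth[!from_tail] <- if (length(body) > 0) {
        sample(body, n_body, replace = TRUE)
      } else {
        rpareto(n_body, fit$alpha, fit$xmin)
      }
    }
    bf <- tryCatch(
      fit_power_law(synth, min_tail = fit$settings$min_tail,
                    max_candidates = fit$settings$max_candidates,
                    compare = character()),
      error = function(e) NULL
    )
    if (is.null(bf)) NA_real_ else bf$ks
  }, 0)
  ks_b <- ks_b[!is.na(ks_b)]
  fit$gof_p <- mean(ks_b >= fit$ks)
  fit$boot_ks <- ks_b
  fit
}

#' Log-log slope of the complementary cumulative distribution
#'
#' Least-squares slope of `log10 P(X >= x)` against `log10 x` over the
#' scaling range -- the exponent a straight edge drawn along the cumulative
#' plot would have. The CCDF is evaluated at log-spaced points (equal weight
#' per unit of log-duration, as the plot is read) between `xmin` and `xmax`;
#' by default `xmax` is the largest value still supported by at least 10
#' observations, so the sparse extreme tail does not dominate the fit. For
#' an exact Pareto tail with density exponent `alpha` the slope is
#' `-(alpha - 1)`.
#'
#' @param x Positive durations (or data frame with `duration_seconds`).
#' @param xmin Lower end of the scaling range; default the KS-selected cutoff
#'   of [fit_power_law()].
#' @param xmax Upper end of the scaling range; default the largest value with
#'   `ccdf >= 10 / length(x)`.
#' @param n_grid Number of log-spaced evaluation points (default 25).
#' @return The slope (negative for a decaying tail).
#' @export
ccdf_slope <- function(x, xmin = NULL, xmax = NULL, n_grid = 25) {
  if (is.data.frame(x)) x <- x$duration_seconds
  if (is.null(xmin)) xmin <- fit_power_law(x, compare = character())$xmin
  cc <- empirical_ccdf(x)
  if (is.null(xmax)) {
    ok <- cc$value[cc$ccdf >= 10 / length(x)]
    xmax <- if (length(ok)) max(ok) else max(cc$value)
  }
  if (xmax <= xmin) abort("Empty scaling range: xmax <= xmin.")
  g <- 10^seq(log10(xmin), log10(xmax), length.out = n_grid)
  y <- stats::approx(log10(cc$value), log10(cc$ccdf), xout = log10(g),
                     rule = 2)$y
  unname(coef(lm(y ~ log10(g)))[2])
}
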