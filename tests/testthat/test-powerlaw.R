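test_that("empirical CCDF matches a brute-force count, ties included", {
  set.seed(11)
  x <- sample(c(1, 2, 2, 3, 5, 5, 5, 8), 40, replace = TRUE)
  cc <- empirical_ccdf(x)
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$ccdf[i], mean(x >= cc$value[i]))
  }
  expect_equal(cc$ccdf[1], 1)
  expect_true(all(diff(cc$ccdf) < 0))
})

test_that("the MLE recovers a known Pareto exponent", {
  set.seed(12)
  x <- rpareto_ref(1e4, alpha = 2.5, xmin = 1)
  fit <- fit_power_law(x, compare = character())
  expect_lt(abs(fit$alpha - 2.5), 0.1)
  expect_true(fit$ks >= 0 && fit$ks <= 1)
  expect_gt(fit$alpha, 1)
})

test_that("the fit is invariant under permutation and duplication-stable", {
  set.seed(13)
  x <- rpareto_ref(2000, 2.2, 0.5)
  f1 <- fit_power_law(x, compare = character())
  f2 <- fit_power_law(sample(x), compare = character())
  expect_equal(f1$alpha, f2$alpha)
  expect_equal(f1$xmin, f2$xmin)
  f3 <- fit_power_law(c(x, x), compare = character())
  expect_equal(f3$alpha, f1$alpha, tolerance = 1e-10)
})

test_that("rescaling durations moves xmin but not the exponent", {
  set.seed(14)
  x <- rpareto_ref(3000, 2.8, 1)
  f1 <- fit_power_law(x, compare = character())
  f2 <- fit_power_law(200 * x, compare = character())
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-9)
  expect_equal(f2$xmin, 200 * f1$xmin, tolerance = 1e-9)
})

test_that("the closed-form MLE agrees with a brute-force likelihood grid", {
  set.seed(15)
  grid <- seq(1.01, 6, by = 0.01)
  for (rep in 1:5) {
    x <- rpareto_ref(sample(100:1000, 1), runif(1, 1.8, 3.5), 1)
    xmin <- quantile(x, 0.2, names = FALSE)
    tl <- x[x >= xmin]
    ll <- vapply(grid, function(a) {
      sum(log(a - 1) - log(xmin) - a * log(tl / xmin))
    }, 0)
    fit <- fit_power_law(x, xmin = xmin, compare = character())
    expect_lt(abs(fit$alpha - grid[which.max(ll)]), 0.011)
  }
})

test_that("exponent estimates are tight over repeated sampling", {
  set.seed(16)
  err <- vapply(1:20, function(r) {
    fit_power_law(rpareto_ref(5000, 2.5, 1), xmin = 1,
                  compare = character())$alpha - 2.5
  }, 0)
  expect_lt(mean(abs(err)), 0.05)
})

test_that("likelihood ratios point at the true generating family", {
  set.seed(17)
  xe <- 1 + rexp(1e4, 2)
  fe <- fit_power_law(xe, xmin = 1)
  lr_exp <- fe$compare$lr[fe$compare$alternative == "exponential"]
  expect_lt(lr_exp, 0) # negative: the exponential fits better
  expect_lt(fe$compare$p[fe$compare$alternative == "exponential"], 0.05)

  xp <- rpareto_ref(1e4, 2.5, 1)
  fp <- fit_power_law(xp, xmin = 1)
  expect_gt(fp$compare$lr[fp$compare$alternative == "exponential"], 0)
})

test_that("tiny or degenerate inputs raise informative errors", {
  expect_error(fit_power_law(rpareto_ref(5, 2.5, 1)), "Too few")
  expect_error(fit_power_law(c(1, 2, -1, rep(2, 20))), "positive")
  err <- tryCatch(fit_power_law(rpareto_ref(100, 2.5, 1), xmin = 1e6),
                  condition = identity)
  expect_s3_class(err, "plicrit_tail_error")
  expect_equal(err$n_tail, 0)
})

test_that("delta vanishes on self-reference and keys on the tail", {
  set.seed(18)
  fit <- fit_power_law(rpareto_ref(3000, 2.5, 1), compare = character())
  # evaluate the reference at its own quantiles: delta must be ~0 within 1/n
  n <- 1000
  q <- fit$xmin * (1 - (1:n - 0.5) / n)^(-1 / (fit$alpha - 1))
  expect_lt(abs(compute_delta(q, fit)$delta), 1 / sqrt(n))

  base <- rpareto_ref(3000, 2.5, 1)
  # appending long durations inflates the tail: delta > 0
  heavy <- c(base, rep(max(base) * 10, 300))
  expect_gt(compute_delta(heavy, fit)$delta, 0)
  # removing everything above the median depletes it: delta < 0
  light <- base[base <= median(base)]
  expect_lt(compute_delta(light, fit)$delta, 0)
})

test_that("delta errors on an empty tail", {
  set.seed(19)
  fit <- fit_power_law(rpareto_ref(500, 2.5, 1), xmin = 1,
                       compare = character())
  expect_error(compute_delta(numeric(0), fit), "Empty")
  expect_error(compute_delta(c(0.1, 0.5), fit), "xmin")
})

test_that("bootstrap goodness-of-fit is calibrated and has power", {
  set.seed(20)
  expect_error(ks_gof(fit_power_law(rpareto_ref(200, 2.5, 1)), n_boot = 0),
               "at least 100")

  # size: data generated from the fitted model itself is rarely rejected
  rejections <- vapply(1:50, function(r) {
    f <- fit_power_law(rpareto_ref(500, 2.5, 1), compare = character())
    ks_gof(f, n_boot = 100)$gof_p < 0.1
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.10), 0.07)

  # power: strongly bimodal data is rejected
  xb <- c(rnorm(5000, 1, 0.05), rnorm(5000, 10, 0.5))
  xb <- xb[xb > 0]
  fb <- fit_power_law(xb, compare = character())
  expect_lt(ks_gof(fb, n_boot = 100)$gof_p, 0.05)
})

test_that("the log-log CCDF slope of a Pareto tail is -(alpha - 1)", {
  set.seed(21)
  x <- rpareto_ref(2e4, 2.5, 1)
  expect_lt(abs(ccdf_slope(x, xmin = 1) - (-1.5)), 0.1)
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(22)
  fit <- fit_power_law(rpareto_ref(2000, 2.5, 1))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "xmin"))
  gl <- glance(fit)
  expect_true(all(c("alpha", "xmin", "ks", "n_tail", "gof_p",
                    "lr_exponential", "lr_lognormal") %in% names(gl)))
  expect_equal(gl$alpha, fit$alpha)
})
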