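test_that("dyadic scales map to the documented frequency bands", {
  expect_equal(scale_band(2, 200), c(25, 50))
  expect_equal(scale_band(3, 200), c(12.5, 25))
  expect_equal(scale_band(4, 200), c(6.25, 12.5))
  expect_equal(scale_band(2, 256), c(32, 64))
})

test_that("a sinusoid's energy concentrates in its own scale", {
  t <- seq(0, 10, by = 1 / 200)
  x <- sin(2 * pi * 30 * t) # 30 Hz sits in scale 2 (25-50 Hz) at 200 Hz
  w <- hilbert_wavelet_transform(x, fs = 200, scales = 2:4)
  en <- vapply(w$coefs, function(z) mean(Mod(z)^2), 0)
  expect_gt(en[["2"]], 10 * en[["4"]])
  expect_gt(en[["2"]], 10 * en[["3"]])
})

test_that("the transform is linear: zero in, zero out", {
  w <- hilbert_wavelet_transform(numeric(512), fs = 200, scales = 1:4)
  for (z in w$coefs) expect_equal(max(Mod(z)), 0)
})

test_that("signals too short for the deepest scale are rejected by name", {
  expect_error(hilbert_wavelet_transform(rnorm(60), 200, scales = 4), "64")
  expect_silent(hilbert_wavelet_transform(rnorm(64), 200, scales = 4))
})

test_that("the phase vector has unit modulus and coherence stays in [0,1]", {
  set.seed(5)
  wx <- hilbert_wavelet_transform(rnorm(4096), 200, 2:3)
  wy <- hilbert_wavelet_transform(rnorm(4096), 200, 2:3)
  pp <- phase_pair_series(wx, wy, scale = 2)
  nz <- Mod(pp$c) > 0
  expect_true(all(abs(Mod(pp$c[nz]) - 1) < 1e-12))
  expect_true(all(pp$coherence >= 0 & pp$coherence <= 1))
  expect_true(all(pp$dphi > -pi & pp$dphi <= pi, na.rm = TRUE))
})

test_that("a signal paired with itself is perfectly coherent at zero lag", {
  x <- sin(2 * pi * 30 * seq(0, 5, by = 1 / 200)) + 0.05 * rnorm(1001)
  w <- hilbert_wavelet_transform(x, 200, 2)
  pp <- phase_pair_series(w, w, scale = 2)
  interior <- pp$sig
  expect_true(any(interior))
  expect_true(all(abs(pp$dphi[interior]) < 1e-10))
  expect_true(all(pp$coherence[interior] > 1 - 1e-10))
})

test_that("swapping the inputs negates the phase difference everywhere", {
  set.seed(6)
  wx <- hilbert_wavelet_transform(rnorm(2048), 200, 2)
  wy <- hilbert_wavelet_transform(rnorm(2048), 200, 2)
  a <- phase_pair_series(wx, wy, 2)
  b <- phase_pair_series(wy, wx, 2)
  ok <- !is.na(a$dphi) & abs(abs(a$dphi) - pi) > 1e-8 # excl. the +pi boundary
  expect_equal(a$dphi[ok], -b$dphi[ok], tolerance = 1e-10)
})

test_that("independent white noise rarely passes the coherence gate", {
  set.seed(7)
  wx <- hilbert_wavelet_transform(rnorm(20000), 200, 2)
  wy <- hilbert_wavelet_transform(rnorm(20000), 200, 2)
  pp <- phase_pair_series(wx, wy, scale = 2, avg_window = 32)
  expect_lt(median(pp$coherence[100:19900]), 0.5)
  expect_lt(mean(pp$sig), 0.5)
})

test_that("mismatched grids and absent scales are rejected", {
  wx <- hilbert_wavelet_transform(rnorm(1024), 200, 2)
  wy <- hilbert_wavelet_transform(rnorm(512), 200, 2)
  expect_error(phase_pair_series(wx, wy, 2), "time grid")
  wz <- hilbert_wavelet_transform(rnorm(1024), 200, 3)
  expect_error(phase_pair_series(wx, wz, 2), "Scale")
})

test_that("interval extraction matches constructed lock patterns exactly", {
  # constant zero phase difference: one interval covering the record
  pp <- make_pps(rep(0, 500))
  pli <- extract_pli(pp)
  expect_equal(pli$duration_samples, 500L)
  expect_equal(pli$duration_seconds, 2.5)

  # constant pi/2 offset against a pi/4 threshold: nothing locks
  expect_equal(nrow(extract_pli(make_pps(rep(pi / 2, 300)),
                                lock_threshold = pi / 4)), 0)

  # alternating locked/unlocked blocks of known lengths
  blocks <- c(12L, 5L, 40L, 3L, 7L, 60L, 1L)
  lockvals <- rep(c(0, 2), length.out = length(blocks))
  dphi <- rep(lockvals, times = blocks)
  pli <- extract_pli(make_pps(dphi), lock_threshold = pi / 4)
  expect_equal(pli$duration_samples, blocks[lockvals == 0])
})

test_that("interval extraction agrees with a naive scan on random masks", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(100:10000, 1)
    locked <- runif(n) < runif(1, 0.2, 0.8)
    dphi <- ifelse(locked, 0, pi)
    pli <- extract_pli(make_pps(dphi), lock_threshold = pi / 4)
    expect_equal(pli$duration_samples, naive_runs(locked))
  }
})

test_that("locked time is monotone in the threshold and the coherence gate", {
  set.seed(9)
  x <- sin(2 * pi * 30 * seq(0, 20, by = 1 / 200))
  wx <- hilbert_wavelet_transform(x + 0.8 * rnorm(4001), 200, 2)
  wy <- hilbert_wavelet_transform(x + 0.8 * rnorm(4001), 200, 2)
  tot <- function(thr, coh) {
    pp <- phase_pair_series(wx, wy, 2, min_coherence = coh)
    sum(extract_pli(pp, lock_threshold = thr)$duration_samples)
  }
  locked_by_thr <- vapply(c(0.2, 0.5, 1, 2, 3), tot, 0, coh = 0.5)
  expect_true(all(diff(locked_by_thr) >= 0))
  locked_by_coh <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), tot, 0, thr = pi / 4)
  expect_true(all(diff(locked_by_coh) <= 0))
})

test_that("a constant small phase offset yields one near-record-long lock", {
  t <- seq(0, 20, by = 1 / 200)
  wx <- hilbert_wavelet_transform(sin(2 * pi * 30 * t), 200, 2)
  wy <- hilbert_wavelet_transform(sin(2 * pi * 30 * t - 0.3), 200, 2)
  pli <- extract_pli(phase_pair_series(wx, wy, 2), lock_threshold = pi / 4)
  expect_equal(nrow(pli), 1)
  n <- length(t)
  expect_gte(pli$duration_samples, n - 2 * 2^(2 + 2) - 8)
})

test_that("PLI tables survive the TSV round trip", {
  pp <- make_pps(rep(c(0, 2), times = c(30, 10)))
  pli <- extract_pli(pp, pair_id = "a-b", window_id = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pli_tsv(pli, path)
  back <- read_pli_tsv(path)
  expect_equal(back$duration_samples, pli$duration_samples)
  expect_equal(back$pair_id, pli$pair_id)
  expect_equal(back$window_id, pli$window_id)
})
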