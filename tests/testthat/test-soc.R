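test_that("network initialization places exactly the requested links", {
  net0 <- soc_network(4, 0)
  expect_equal(length(net0$tgt), 0)
  expect_equal(soc_connectivity(net0), 0)

  net <- soc_network(1024, 2, seed = 41)
  expect_equal(length(net$tgt), 2048)
  expect_equal(soc_connectivity(net), 2)
  expect_true(all(net$tgt != net$src))           # no self-links
  expect_false(any(duplicated(cbind(net$tgt, net$src))))
  expect_true(all(net$sgn %in% c(-1L, 1L)))
  expect_true(all(net$sigma %in% c(-1L, 1L)))

  expect_identical(soc_network(64, 1.5, seed = 7),
                   soc_network(64, 1.5, seed = 7))
  expect_error(soc_network(10, 10), "k_init")
})

test_that("the zero-field convention sends unconnected nodes to -1", {
  net <- soc_network(8, 0, seed = 42)
  net <- step_dynamics(net)
  expect_true(all(net$sigma == -1L))
  net <- step_dynamics(net)
  expect_true(all(net$sigma == -1L))
})

test_that("a mutually excitatory aligned pair is a fixed point", {
  net <- soc_network(2, 0, seed = 43)
  net$tgt <- c(1L, 2L); net$src <- c(2L, 1L); net$sgn <- c(1L, 1L)
  net$sigma <- c(1L, 1L)
  expect_equal(step_dynamics(net)$sigma, c(1L, 1L))
})

test_that("the compiled update kernel matches a per-node loop oracle", {
  set.seed(44)
  for (rep in 1:100) {
    net <- soc_network(64, runif(1, 0.5, 4))
    expect_identical(step_dynamics(net)$sigma, naive_step(net))
  }
})

test_that("epoch activity flags record any state change", {
  # zero-coupling network: after the first settling step nothing moves
  net <- soc_network(16, 0, seed = 45)
  settled <- run_epoch(net, 1)$net
  ep <- run_epoch(settled, 5)
  expect_false(any(ep$changed))

  # T = 1 equals a one-step comparison
  net <- soc_network(32, 2, seed = 46)
  before <- net$sigma
  ep <- run_epoch(net, 1)
  expect_equal(ep$changed, ep$net$sigma != before)

  # a period-2 oscillator pair is active for any T >= 2
  osc <- soc_network(2, 0, seed = 47)
  osc$tgt <- c(1L, 2L); osc$src <- c(2L, 1L); osc$sgn <- c(1L, 1L)
  osc$sigma <- c(1L, -1L)
  expect_true(all(run_epoch(osc, 2)$changed))
  expect_true(all(run_epoch(osc, 17)$changed))
})

test_that("adaptive rewiring grows frozen nodes and prunes active ones", {
  net <- soc_network(16, 1, seed = 48)
  # frozen node: gains exactly one incoming link
  n1 <- rewire_adaptive(net, changed = rep(FALSE, 16), node = 5)
  expect_equal(length(n1$tgt), length(net$tgt) + 1)
  expect_equal(tail(n1$tgt, 1), 5L)
  expect_true(tail(n1$src, 1) != 5L)

  # active node with exactly one incoming link: loses it
  net2 <- soc_network(8, 0, seed = 49)
  net2$tgt <- 3L; net2$src <- 7L; net2$sgn <- 1L
  n2 <- rewire_adaptive(net2, changed = rep(TRUE, 8), node = 3)
  expect_equal(length(n2$tgt), 0)

  # impossible moves leave the network unchanged
  n3 <- rewire_adaptive(net2, changed = rep(TRUE, 8), node = 5) # no in-links
  expect_equal(length(n3$tgt), 1)
  sat <- soc_network(3, 2, seed = 50) # every node saturated (K = n - 1)
  n4 <- rewire_adaptive(sat, changed = rep(FALSE, 3), node = 1)
  expect_equal(length(n4$tgt), 6)
})

test_that("any topology update changes the link count by at most one", {
  set.seed(51)
  net <- soc_network(32, 1.5)
  for (i in 1:200) {
    ep <- run_epoch(net, 20)
    m0 <- length(net$tgt)
    net <- if (i %% 2) rewire_adaptive(ep$net, ep$changed)
           else rewire_random(ep$net, 0.5, 0.5)
    expect_lte(abs(length(net$tgt) - m0), if (i %% 2) 1L else 2L)
    expect_true(all(net$tgt != net$src))
    expect_false(any(duplicated(cbind(net$tgt, net$src))))
  }
})

test_that("probability-driven rewiring follows its probabilities", {
  set.seed(52)
  net <- soc_network(64, 1)
  n1 <- rewire_random(net, p_add = 1, p_del = 0)
  expect_equal(length(n1$tgt), length(net$tgt) + 1)
  n2 <- rewire_random(net, p_add = 0, p_del = 0)
  expect_identical(n2$tgt, net$tgt)
  n3 <- rewire_random(net, p_add = 0, p_del = 1)
  expect_equal(length(n3$tgt), length(net$tgt) - 1)
})

test_that("trajectories are reproducible from (seed, config)", {
  t1 <- soc_run(64, 1.5, iterations = 50, t_epoch = 50, seed = 53)
  t2 <- soc_run(64, 1.5, iterations = 50, t_epoch = 50, seed = 53)
  expect_identical(t1$k_series, t2$k_series)
  expect_identical(t1$net$sigma, t2$net$sigma)
})

test_that("random-mode drift direction follows p_add - p_del", {
  t_up <- soc_run(128, 2, iterations = 300, t_epoch = 20, mode = "random",
                  p_add = 0.9, p_del = 0.1, seed = 54)
  t_dn <- soc_run(128, 2, iterations = 300, t_epoch = 20, mode = "random",
                  p_add = 0.1, p_del = 0.9, seed = 54)
  expect_gt(tail(t_up$k_series$k, 1), 2 + 0.5)
  expect_lt(tail(t_dn$k_series$k, 1), 2 - 0.5)
})

test_that("the frozen component is 1 for empty graphs and counts cycles", {
  expect_equal(frozen_component(soc_network(16, 0, seed = 55), 10, 10), 1)

  # one period-2 pair among otherwise isolated nodes: (N-2)/N
  net <- soc_network(16, 0, seed = 56)
  net$tgt <- c(1L, 2L); net$src <- c(2L, 1L); net$sgn <- c(1L, 1L)
  net$sigma[1:2] <- c(1L, -1L)
  expect_equal(frozen_component(net, 10, 10), 14 / 16)
})

test_that("the order parameter separates the frozen and chaotic phases", {
  set.seed(57)
  low <- mean(vapply(1:3, function(i) {
    frozen_component(soc_network(1024, 1), 500, 500)
  }, 0))
  high <- mean(vapply(1:3, function(i) {
    frozen_component(soc_network(1024, 4), 500, 500)
  }, 0))
  expect_gt(low, 0.9)
  expect_lt(high, 0.1)
})

test_that("permanently identical monitored nodes give one maximal PLI", {
  # two nodes sharing an alternating state series, long enough for scale 1
  s <- rep(c(1L, -1L), 200)
  traj <- structure(
    list(states = cbind(s, s), monitor = c(1L, 2L), net = NULL,
         k_series = tibble::tibble(iteration = 1, k = 0, frozen_frac = 0),
         config = list(t_epoch = length(s), n_nodes = 2)),
    class = "soc_trajectory")
  pli <- model_pli(traj, scale = 1)
  expect_equal(nrow(pli), 1)
  expect_gte(pli$duration_samples, length(s) - 2 * 2^3 - 4)
})

test_that("model PLI demands recorded states", {
  t0 <- soc_run(32, 1, iterations = 5, t_epoch = 10, seed = 58)
  expect_error(model_pli(t0), "recorded")
  t1 <- soc_run(32, 1, iterations = 5, t_epoch = 10, record_nodes = 3,
                record_from = 1, seed = 58)
  expect_error(model_pli(t1, n_iterations = 50), "epochs")
})
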