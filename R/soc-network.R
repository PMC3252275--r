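#' Random adaptive threshold network
#'
#' Initializes a network of `n_nodes` binary elements with states in
#' `{-1, +1}` and `round(n_nodes * k_init)` directed links placed uniformly at
#' random (no self-links, no duplicate links), each carrying a random sign
#' `+1` or `-1`. Mean connectivity is the number of links per node.
#'
#' @param n_nodes Number of nodes (>= 2).
#' @param k_init Initial mean connectivity (links per node), in
#'   `[0, n_nodes - 1]`.
#' @param seed Optional integer seed (sets R's RNG).
#' @return Object of class `soc_network`: list with `n`, `sigma` (states),
#'   and parallel link vectors `tgt`, `src`, `sgn` (incoming links
#'   `src -> tgt` with sign `sgn`).
#' @export
soc_network <- function(n_nodes, k_init, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2) abort("`n_nodes` must be >= 2.")
  if (k_init < 0 || k_init > n_nodes - 1) {
    abort("`k_init` must lie in [0, n_nodes - 1].")
  }
  m <- round(n_nodes * k_init)
  # ordered pairs (tgt, src), tgt != src, sampled without replacement
  pick <- sample.int(n_nodes * (n_nodes - 1L), m)
  tgt <- as.integer((pick - 1L) %/% (n_nodes - 1L) + 1L)
  off <- as.integer((pick - 1L) %% (n_nodes - 1L) + 1L)
  src <- ifelse(off >= tgt, off + 1L, off)
  structure(
    list(n = n_nodes,
         sigma = sample(c(-1L, 1L), n_nodes, replace = TRUE),
         tgt = tgt, src = as.integer(src),
         sgn = sample(c(-1L, 1L), m, replace = TRUE)),
    class = "soc_network")
}

#' @export
print.soc_network <- function(x, ...) {
  cat(sprintf("<soc_network> %d nodes, %d links (K = %.3f)\n",
              x$n, length(x$tgt), soc_connectivity(x)))
  invisible(x)
}

#' Mean connectivity of a network
#' @param net A [soc_network()].
#' @return Links per node.
#' @export
soc_connectivity <- function(net) length(net$tgt) / net$n

#' Coupling matrix of a network
#' @param net A [soc_network()].
#' @return Dense integer matrix `c` with `c[i, j]` the sign of the link
#'   `j -> i` (0 if absent); zero diagonal.
#' @export
soc_coupling_matrix <- function(net) {
  cm <- matrix(0L, net$n, net$n)
  cm[cbind(net$tgt, net$src)] <- net$sgn
  cm
}

#' One synchronous update of the node states
#'
#' Every node computes its input field `h_i = sum_j c_ij sigma_j` over its
#' incoming links and sets `sigma_i <- sign(h_i)`, with the fixed convention
#' that a zero field maps to `-1` (so isolated nodes settle at `-1`).
#'
#' @param net A [soc_network()].
#' @return The network with updated states.
#' @export
step_dynamics <- function(net) {
  res <- cpp_epoch(net$n, net$tgt, net$src, net$sgn, net$sigma,
                   t_epoch = 1L, monitor = integer(0))
  net$sigma <- res$sigma
  net
}

#' Run one epoch of dynamics
#'
#' Applies `t_epoch` synchronous updates and records, per node, whether its
#' state changed at least once during the epoch -- the activity flag that
#' drives adaptive rewiring.
#'
#' @param net A [soc_network()].
#' @param t_epoch Number of synchronous steps (default 1000).
#' @param monitor Optional integer vector of node ids whose state time series
#'   is recorded.
#' @return List with `net` (updated states), `changed` (logical per node) and
#'   `states` (steps x monitored-nodes integer matrix, possibly 0-column).
#' @export
run_epoch <- function(net, t_epoch = 1000, monitor = integer(0)) {
  stopifnot(t_epoch >= 1)
  res <- cpp_epoch(net$n, net$tgt, net$src, net$sgn, net$sigma,
                   t_epoch = as.integer(t_epoch),
                   monitor = as.integer(monitor))
  net$sigma <- res$sigma
  list(net = net, changed = res$changed, states = res$states)
}

#' Activity-dependent topology update
#'
#' Picks one node uniformly at random (or the given `node`). If the node was
#' frozen during the last epoch (its state never changed) it gains one
#' incoming link from a random distinct source with random sign; if it was
#' active it loses one uniformly chosen incoming link. When the required move
#' is impossible (no link to delete, or the node already receives links from
#' all other nodes) the network is returned unchanged. Over many iterations
#' this rule drives the mean connectivity toward the self-organized plateau.
#'
#' @param net A [soc_network()].
#' @param changed Logical activity flags from [run_epoch()].
#' @param node Optional node id, for deterministic testing.
#' @return The (possibly) rewired network.
#' @export
rewire_adaptive <- function(net, changed, node = NULL) {
  stopifnot(length(changed) == net$n)
  u <- as.integer(node %||% sample.int(net$n, 1))
  incoming <- which(net$tgt == u)
  if (!changed[u]) {
    existing <- net$src[incoming]
    candidates <- setdiff(seq_len(net$n), c(u, existing))
    if (length(candidates) == 0) return(net)
    v <- if (length(candidates) == 1) candidates else sample(candidates, 1)
    net$tgt <- c(net$tgt, u)
    net$src <- c(net$src, v)
    net$sgn <- c(net$sgn, sample(c(-1L, 1L), 1))
  } else {
    if (length(incoming) == 0) return(net)
    k <- if (length(incoming) == 1) incoming else sample(incoming, 1)
    net$tgt <- net$tgt[-k]; net$src <- net$src[-k]; net$sgn <- net$sgn[-k]
  }
  net
}

#' Probability-driven topology update
#'
#' The null counterpart of [rewire_adaptive()]: with probability `p_add` one
#' absent link (uniform target and source, random sign) is added and,
#' independently, with probability `p_del` one uniformly chosen existing link
#' is deleted. Applied once per iteration; node activity plays no role.
#'
#' @param net A [soc_network()].
#' @param p_add,p_del Probabilities in `[0, 1]`.
#' @return The (possibly) rewired network.
#' @export
rewire_random <- function(net, p_add, p_del) {
  stopifnot(p_add >= 0, p_add <= 1, p_del >= 0, p_del <= 1)
  if (runif(1) < p_add && length(net$tgt) < net$n * (net$n - 1)) {
    for (i in 1:10000) {
      u <- sample.int(net$n, 1); v <- sample.int(net$n, 1)
      if (u == v || any(net$tgt == u & net$src == v)) next
      net$tgt <- c(net$tgt, u)
      net$src <- c(net$src, v)
      net$sgn <- c(net$sgn, sample(c(-1L, 1L), 1))
      break
    }
  }
  if (runif(1) < p_del && length(net$tgt) > 0) {
    k <- sample.int(length(net$tgt), 1)
    net$tgt <- net$tgt[-k]; net$src <- net$src[-k]; net$sgn <- net$sgn[-k]
  }
  net
}

#' Frozen component of the dynamics
#'
#' Runs `transient` synchronous steps from the network's current states, then
#' `observe` further steps, and returns the fraction of nodes whose state
#' never changes during the observation stretch -- the order parameter of the
#' frozen/chaotic transition. Attractors are probed by this transient+observe
#' scheme rather than by exact cycle detection.
#'
#' @param net A [soc_network()].
#' @param transient Steps discarded before observing (default 500).
#' @param observe Steps over which state changes are counted (default 500).
#' @return Fraction in `[0, 1]`.
#' @export
frozen_component <- function(net, transient = 500, observe = 500) {
  stopifnot(transient >= 1, observe >= 1)
  a <- run_epoch(net, transient)
  b <- run_epoch(a$net, observe)
  mean(!b$changed)
}

#' Frozen component as a function of connectivity
#'
#' Averages [frozen_component()] over `reps` independent random topologies
#' (fresh random states each) for every requested connectivity.
#'
#' @param k_values Numeric vector of mean connectivities.
#' @param n_nodes Network size (default 1024).
#' @param reps Topologies per connectivity (default 100).
#' @param transient,observe Passed to [frozen_component()].
#' @param seed Optional seed.
#' @return Tibble with `k`, `frozen` (mean), `sd` and `reps`.
#' @export
frozen_sweep <- function(k_values, n_nodes = 1024, reps = 100,
                         transient = 500, observe = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(k_values, function(k) {
    fr <- vapply(seq_len(reps), function(r) {
      frozen_component(soc_network(n_nodes, k), transient, observe)
    }, 0)
    tibble(k = k, frozen = mean(fr), sd = sd(fr), reps = reps)
  })
}
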