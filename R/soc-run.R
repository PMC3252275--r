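#' Simulate the adaptive SOC network
#'
#' Full simulation loop around the compiled synchronous-update kernel:
#' `iterations` epochs of `t_epoch` parallel threshold updates, each followed
#' by one topology update -- either the activity-dependent rule (mode
#' `"adaptive"`: a frozen node gains an incoming link, an active node loses
#' one) or probability-driven link turnover independent of activity (mode
#' `"random"`). Under the adaptive rule the mean connectivity self-organizes
#' to a characteristic plateau independent of `k_init`; under random turnover
#' it drifts with the sign of `p_add - p_del`.
#'
#' By default each epoch starts from a fresh random state vector and the
#' frozen/active decision counts state changes only over the second half of
#' the epoch, so it reflects behavior on the dynamical attractor rather than
#' the settling transient -- the protocol of the adaptive threshold-network
#' model this simulator instantiates. Set `reset_states = FALSE` /
#' `t_transient = 0` to carry states across epochs and count every change.
#'
#' @param n_nodes Network size (default 1024).
#' @param k_init Initial mean connectivity (ignored when `init` is given).
#' @param iterations Number of topology updates (epochs).
#' @param t_epoch Dynamics steps per epoch (default 1000).
#' @param mode `"adaptive"` or `"random"`.
#' @param p_add,p_del Link add/delete probabilities for `"random"` mode.
#' @param record_nodes How many randomly chosen nodes to monitor (0 for
#'   none), or an integer vector of explicit node ids.
#' @param record_from First epoch (1-based) whose monitored states are kept;
#'   default records the final 100 epochs.
#' @param reset_states Re-randomize node states at the start of every epoch
#'   (default `TRUE`).
#' @param t_transient Steps at the start of each epoch excluded from the
#'   activity measurement (default `t_epoch / 2`).
#' @param seed Optional integer seed.
#' @param init Optional [soc_network()] to continue from (topology and states
#'   carried over), e.g. to switch rewiring modes mid-experiment.
#' @return Object of class `soc_trajectory`: list with `k_series` (tibble of
#'   `iteration`, `k`, `frozen_frac`), `states` (steps x monitored-nodes
#'   matrix of recorded -1/+1 states), `monitor` (node ids), `net` (final
#'   network) and `config`.
#' @export
soc_run <- function(n_nodes = 1024, k_init = 2, iterations = 4000,
                    t_epoch = 1000, mode = c("adaptive", "random"),
                    p_add = 0.8, p_del = 0.2,
                    record_nodes = 0, record_from = NULL,
                    reset_states = TRUE, t_transient = NULL,
                    seed = NULL, init = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  net <- init %||% soc_network(n_nodes, k_init)
  stopifnot(inherits(net, "soc_network"))
  n_nodes <- net$n

  monitor <- if (length(record_nodes) > 1 || record_nodes[1] > 0) {
    if (length(record_nodes) == 1) sort(sample.int(n_nodes, record_nodes))
    else sort(as.integer(record_nodes))
  } else integer(0)
  record_from <- as.integer(record_from %||% max(1, iterations - 99))
  t_transient <- as.integer(t_transient %||% (t_epoch %/% 2))
  stopifnot(t_transient >= 0, t_transient < t_epoch)

  res <- cpp_soc_run(net$n, net$tgt, net$src, net$sgn, net$sigma,
                     as.integer(t_epoch), as.integer(iterations),
                     mode_int(mode), p_add, p_del,
                     monitor, record_from,
                     isTRUE(reset_states), t_transient)
  out_net <- structure(list(n = net$n, sigma = res$sigma, tgt = res$tgt,
                            src = res$src, sgn = res$sgn),
                       class = "soc_network")
  structure(
    list(k_series = tibble(iteration = seq_len(iterations),
                           k = res$k_series,
                           frozen_frac = res$frozen_frac),
         states = res$states, monitor = monitor, net = out_net,
         config = list(n_nodes = n_nodes, k_init = k_init,
                       iterations = iterations, t_epoch = t_epoch,
                       mode = mode, p_add = p_add, p_del = p_del,
                       record_from = record_from,
                       reset_states = isTRUE(reset_states),
                       t_transient = t_transient, seed = seed)),
    class = "soc_trajectory")
}

mode_int <- function(mode) if (mode == "adaptive") 0L else 1L

#' @export
print.soc_trajectory <- function(x, ...) {
  ks <- x$k_series$k
  cat(sprintf(
    "<soc_trajectory> %d nodes, %d iterations (%s rewiring)\n  K: start %.3f -> final %.3f; %d monitored nodes\n",
    x$config$n_nodes, x$config$iterations, x$config$mode,
    ks[1], ks[length(ks)], length(x$monitor)))
  invisible(x)
}

#' Plateau connectivity of a trajectory
#'
#' Mean of the connectivity series over the final `last` topology updates,
#' the standard summary of where the adaptive rule has settled.
#'
#' @param traj A [soc_run()] trajectory.
#' @param last Number of final iterations to average (default 500).
#' @return Mean connectivity (links per node).
#' @export
plateau_connectivity <- function(traj, last = 500) {
  ks <- traj$k_series$k
  stopifnot(length(ks) >= last)
  mean(tail(ks, last))
}

#' Phase-lock intervals between monitored model nodes
#'
#' Treats the recorded -1/+1 state series of each monitored node,
#' concatenated across the recorded epochs, as a real-valued signal sampled
#' at 1 step^-1, runs the package's analytic-wavelet phase estimator at the
#' given scale, and pools phase-lock interval durations over all unordered
#' node pairs. Durations are in dynamics steps.
#'
#' @param traj A [soc_run()] trajectory with monitored nodes.
#' @param scale Wavelet scale (default 1, the band of periods 2--4 steps).
#' @param n_iterations Use only the first `n_iterations` recorded epochs
#'   (default: all recorded).
#' @param lock_threshold,min_coherence,avg_window,edge_trim Passed to the
#'   phase estimator (defaults as in [phase_pair_series()] /
#'   [extract_pli()]).
#' @return PLI tibble as from [window_pli()] (durations in steps;
#'   `duration_seconds` is steps at the unit rate).
#' @export
model_pli <- function(traj, scale = 1, n_iterations = NULL,
                      lock_threshold = pi / 4, min_coherence = 0.5,
                      avg_window = NULL, edge_trim = NULL) {
  stopifnot(inherits(traj, "soc_trajectory"))
  st <- traj$states
  if (is.null(st) || length(st) == 0 || ncol(st) < 2) {
    abort("Trajectory has no recorded node states (need >= 2 monitored nodes).")
  }
  t_epoch <- traj$config$t_epoch
  if (!is.null(n_iterations)) {
    need <- n_iterations * t_epoch
    if (nrow(st) < need) {
      abort(sprintf("Recorded states cover %d epochs; %d requested.",
                    nrow(st) %/% t_epoch, n_iterations))
    }
    st <- st[seq_len(need), , drop = FALSE]
  }
  n_ch <- ncol(st)
  hw <- lapply(seq_len(n_ch), function(ch) {
    hilbert_wavelet_transform(as.numeric(st[, ch]), fs = 1, scales = scale)
  })
  pairs <- channel_pairs(n_ch)
  labels <- sprintf("node%04d", traj$monitor)
  purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    i <- pairs[p, 1]; k <- pairs[p, 2]
    pps <- phase_pair_series(hw[[i]], hw[[k]], scale = scale,
                             avg_window = avg_window,
                             min_coherence = min_coherence,
                             edge_trim = edge_trim)
    extract_pli(pps, lock_threshold = lock_threshold,
                pair_id = paste(labels[i], labels[k], sep = "-"))
  })
}

#' Write a trajectory to JSON
#'
#' Serializes the connectivity/frozen series, the configuration and the
#' monitored node ids (not the bulky state matrix) for downstream plotting.
#'
#' @param traj A [soc_run()] trajectory.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_json <- function(traj, path) {
  jsonlite::write_json(
    list(config = traj$config, monitor = traj$monitor,
         k_series = traj$k_series),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
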