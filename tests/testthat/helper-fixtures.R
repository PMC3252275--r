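# Shared fixture builders (everything is generated in code at test time).

# A phase_pair_series built directly from a phase-difference and coherence
# series, bypassing the wavelet stage, so interval extraction can be tested
# against exactly known run patterns.
make_pps <- function(dphi, coherence = rep(1, length(dphi)), fs = 200,
                     scale = 2, min_coherence = 0.5, edge_trim = 0) {
  n <- length(dphi)
  csm <- complex(modulus = sqrt(coherence), argument = dphi)
  sig <- coherence > min_coherence
  if (edge_trim > 0) {
    sig[seq_len(min(edge_trim, n))] <- FALSE
    sig[n - seq_len(min(edge_trim, n)) + 1] <- FALSE
  }
  out <- tibble::tibble(
    t = seq_len(n),
    c = complex(modulus = 1, argument = dphi),
    c_smooth = csm, dphi = dphi, coherence = coherence, sig = sig)
  structure(out, class = c("phase_pair_series", class(out)),
            scale = scale, fs = fs, avg_window = 1L,
            min_coherence = min_coherence, edge_trim = edge_trim)
}

# Naive run-length oracle: scan a logical vector and collect TRUE-run lengths.
naive_runs <- function(x) {
  out <- integer(0); cur <- 0L
  for (v in x) {
    if (isTRUE(v)) cur <- cur + 1L
    else if (cur > 0L) { out <- c(out, cur); cur <- 0L }
  }
  if (cur > 0L) out <- c(out, cur)
  out
}

# Naive per-node threshold update (the dynamics oracle).
naive_step <- function(net) {
  cm <- soc_coupling_matrix(net)
  s_new <- integer(net$n)
  for (i in seq_len(net$n)) {
    h <- sum(cm[i, ] * net$sigma)
    s_new[i] <- if (h > 0) 1L else -1L
  }
  s_new
}

# Pareto sampler used as an independent source of test data (inverse CDF).
rpareto_ref <- function(n, alpha, xmin) xmin * (1 - runif(n))^(-1 / (alpha - 1))

# A tiny two-regime surrogate recording for fast pipeline tests.
quick_recording <- function(seed = 1, duration_s = 60, n_channels = 4,
                            fs = 200) {
  generate_recording(synth_config(
    n_channels = n_channels, fs = fs,
    regimes = regime("baseline", duration_s), seed = seed))
}
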