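#' Regime specification for the surrogate generator
#'
#' One homogeneous stretch of a surrogate recording. `baseline` produces
#' scale-free phase locking with locked dwell times drawn from a power law
#' with density exponent `target_alpha`; `seizure` multiplies locked dwell
#' durations by `lock_excess` (an excess of long locking); `recovery` lets
#' the excess decay exponentially back toward 1 with time constant
#' `relax_tau_s`.
#'
#' @param name `"baseline"`, `"seizure"` or `"recovery"`.
#' @param duration_s Regime duration in seconds (> 0).
#' @param target_alpha Locked-dwell power-law density exponent (> 1,
#'   default 2.5; the printed cumulative slope is `-(target_alpha - 1)`).
#' @param lock_excess Multiplier on locked dwell durations (>= 1; only used
#'   by `seizure`, default 8).
#' @param relax_tau_s Relaxation time constant in seconds (`recovery` only,
#'   default 30).
#' @return A one-row tibble.
#' @export
regime <- function(name = c("baseline", "seizure", "recovery"),
                   duration_s, target_alpha = 2.5, lock_excess = 8,
                   relax_tau_s = 30) {
  name <- match.arg(name)
  if (duration_s <= 0) abort("`duration_s` must be > 0.")
  if (target_alpha <= 1) abort("`target_alpha` must be > 1.")
  if (lock_excess < 1) abort("`lock_excess` must be >= 1.")
  tibble(name = name, duration_s = duration_s,
         target_alpha = target_alpha, lock_excess = lock_excess,
         relax_tau_s = relax_tau_s)
}

#' Configuration of the surrogate multichannel generator
#'
#' @param n_channels Number of channels (>= 2, default 8).
#' @param fs Sampling rate in Hz (default 200).
#' @param carrier_band Two-element Hz interval for the common narrowband
#'   carrier; must sit inside `(0, fs/2)`. The default 30--40 Hz falls in
#'   wavelet scale 2 at 200 Hz.
#' @param regimes Tibble of [regime()] rows, applied in order.
#' @param noise_sigma Additive white-noise standard deviation relative to the
#'   unit-amplitude carrier (default 0.1).
#' @param locked_xmin_s Lower cutoff of the locked-dwell power law in
#'   seconds (default 0.05).
#' @param unlocked_mean_s Mean of the exponential part of the unlocked
#'   dwells in seconds (default 0.2).
#' @param unlocked_min_s Refractory floor added to every unlocked dwell
#'   (default 0.15 s), guaranteeing that an unlock is long enough for the
#'   phase estimator to resolve it at the analysis scale.
#' @param jitter_sd Within-lock phase jitter SD in radians (default 0.05).
#' @param detune_hz Maximum magnitude of per-episode detuning during
#'   unlocked stretches, in Hz (default 4); episode detunings are drawn
#'   from `[detune_hz/2, detune_hz]` with random sign, so the phase
#'   difference always sweeps through the lock region quickly instead of
#'   lingering there and faking short locks.
#' @param seed Optional integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 8, fs = 200, carrier_band = c(30, 40),
                         regimes = regime("baseline", 600),
                         noise_sigma = 0.1, locked_xmin_s = 0.05,
                         unlocked_mean_s = 0.2, unlocked_min_s = 0.15,
                         jitter_sd = 0.05, detune_hz = 4, seed = NULL) {
  if (n_channels < 2) abort("`n_channels` must be >= 2.")
  if (length(carrier_band) != 2 || carrier_band[1] <= 0 ||
      carrier_band[2] >= fs / 2 || carrier_band[1] >= carrier_band[2]) {
    abort("`carrier_band` must lie inside (0, fs/2) with low < high.")
  }
  stopifnot(nrow(regimes) >= 1)
  structure(
    list(n_channels = n_channels, fs = fs, carrier_band = carrier_band,
         regimes = regimes, noise_sigma = noise_sigma,
         locked_xmin_s = locked_xmin_s, unlocked_mean_s = unlocked_mean_s,
         unlocked_min_s = unlocked_min_s, jitter_sd = jitter_sd,
         detune_hz = detune_hz, seed = seed),
    class = "synth_config")
}

#' Sample locked dwell times from a power law
#'
#' Inverse-CDF draws from the continuous Pareto with density exponent
#' `alpha` and lower cutoff `xmin`: `x = xmin * (1 - u)^(-1/(alpha - 1))`.
#' These are the ground-truth locked dwell times of the generator.
#'
#' @param n Number of draws (0 gives an empty vector).
#' @param alpha Density exponent (> 1).
#' @param xmin Lower cutoff (> 0).
#' @return Numeric vector of durations, all `>= xmin`.
#' @export
#' @examples
#' # analytic check: alpha = 2, xmin = 1, u = 0.75 maps to (0.25)^-1 = 4
#' mean(dwell_time_sampler(1e4, alpha = 3, xmin = 1)) # ~ (3-1)/(3-2) = 2
dwell_time_sampler <- function(n, alpha, xmin) {
  if (alpha <= 1) abort("`alpha` must be > 1.")
  if (xmin <= 0) abort("`xmin` must be > 0.")
  if (n == 0) return(numeric(0))
  qpareto(runif(n), alpha, xmin)
}

# Piecewise lock-excess multiplier per sample, following the regime order:
# baseline 1, seizure lock_excess, recovery exponential decay toward 1 from
# the level at regime entry.
excess_timeline <- function(cfg, n_total) {
  fs <- cfg$fs
  ex <- numeric(n_total)
  alpha <- numeric(n_total)
  cursor <- 0L
  level <- 1
  for (r in seq_len(nrow(cfg$regimes))) {
    rg <- cfg$regimes[r, ]
    len <- min(round(rg$duration_s * fs), n_total - cursor)
    if (len <= 0) break
    idx <- cursor + seq_len(len)
    if (rg$name == "baseline") {
      ex[idx] <- 1
      level <- 1
    } else if (rg$name == "seizure") {
      ex[idx] <- rg$lock_excess
      level <- rg$lock_excess
    } else { # recovery
      t_rel <- (seq_len(len) - 1) / fs
      ex[idx] <- 1 + (level - 1) * exp(-t_rel / rg$relax_tau_s)
      level <- ex[idx[len]]
    }
    alpha[idx] <- rg$target_alpha
    cursor <- cursor + len
  }
  if (cursor < n_total) { # pad with the last regime's parameters
    idx <- (cursor + 1L):n_total
    ex[idx] <- ex[cursor]
    alpha[idx] <- alpha[cursor]
  }
  list(excess = ex, alpha = alpha)
}

#' Generate a surrogate multichannel recording
#'
#' Channels are unit-amplitude narrowband oscillators riding a common
#' carrier. A single renewal process alternates the ensemble between a
#' locked state (all channels track the common phase up to small jitter, so
#' every pair is phase-locked) and an unlocked state (each channel drifts at
#' its own detuned frequency). Locked dwell times are power-law distributed
#' with the regime's `target_alpha`, scaled by the regime's lock-excess
#' multiplier; unlocked dwells are exponential. White measurement noise is
#' added. Regime boundaries and the ground-truth locked episodes are stored
#' in the recording's metadata.
#'
#' @param cfg A [synth_config()].
#' @return An [mc_recording()]; `meta$synth` holds the configuration echo,
#'   regime table and locked-episode table.
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$fs
  n_total <- round(sum(cfg$regimes$duration_s) * fs)
  tl <- excess_timeline(cfg, n_total)

  # common carrier with slow phase drift
  f_c <- mean(cfg$carrier_band)
  phi_c <- 2 * pi * f_c * (seq_len(n_total) - 1) / fs +
    cumsum(rnorm(n_total, 0, 0.005))

  # global locked/unlocked renewal process (durations in samples)
  locked <- logical(n_total)
  ep_start <- integer(0); ep_len <- integer(0)
  cursor <- 0L
  state_locked <- FALSE
  while (cursor < n_total) {
    at <- cursor + 1L
    if (state_locked) {
      d <- dwell_time_sampler(1, tl$alpha[at], cfg$locked_xmin_s) *
        tl$excess[at]
      len <- max(1L, as.integer(round(d * fs)))
      idx <- at:min(n_total, cursor + len)
      locked[idx] <- TRUE
      ep_start <- c(ep_start, at); ep_len <- c(ep_len, length(idx))
    } else {
      d <- cfg$unlocked_min_s + rexp(1, 1 / cfg$unlocked_mean_s)
      len <- max(1L, as.integer(round(d * fs)))
    }
    cursor <- cursor + len
    state_locked <- !state_locked
  }

  # per-channel phase offsets relative to the carrier
  data <- matrix(0, n_total, cfg$n_channels)
  runs <- rle(locked)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  for (ch in seq_len(cfg$n_channels)) {
    # OU jitter while locked
    z <- rnorm(n_total, 0, cfg$jitter_sd * sqrt(1 - 0.98^2))
    jit <- as.numeric(stats::filter(z, 0.98, method = "recursive"))
    psi <- numeric(n_total)
    last <- 0
    for (r in seq_along(runs$values)) {
      idx <- run_start[r]:run_end[r]
      if (runs$values[r]) {
        psi[idx] <- jit[idx]
        last <- psi[run_end[r]]
      } else {
        # phase slip at unlock onset so the pair leaves the lock region at
        # once, then detuned drift plus fast phase diffusion: an unlocked
        # pair is incoherent, so its smoothed phase vector must fall below
        # the coherence gate rather than merely point elsewhere
        slip <- sample(c(-1, 1), 1) * runif(1, pi / 2, pi)
        df <- sample(c(-1, 1), 1) * runif(1, cfg$detune_hz / 2, cfg$detune_hz)
        drift <- cumsum(rep(2 * pi * df / fs, length(idx)) +
                          rnorm(length(idx), 0, 1.0))
        psi[idx] <- last + slip + drift
        last <- psi[run_end[r]]
      }
    }
    data[, ch] <- sin(phi_c + psi) + rnorm(n_total, 0, cfg$noise_sigma)
  }

  bounds <- cumsum(cfg$regimes$duration_s)
  meta <- list(synth = list(
    seed = cfg$seed, fs = fs, carrier_band = cfg$carrier_band,
    noise_sigma = cfg$noise_sigma, locked_xmin_s = cfg$locked_xmin_s,
    unlocked_mean_s = cfg$unlocked_mean_s,
    unlocked_min_s = cfg$unlocked_min_s,
    regimes = data.frame(name = cfg$regimes$name,
                         start_s = c(0, head(bounds, -1)),
                         end_s = bounds,
                         target_alpha = cfg$regimes$target_alpha,
                         lock_excess = cfg$regimes$lock_excess),
    episodes = data.frame(start_sample = ep_start,
                          duration_samples = ep_len)))
  mc_recording(data, fs = fs, start_time = 0, meta = meta)
}
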