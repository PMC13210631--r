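#' Generator configuration for one synthetic session
#'
#' @param length Session length in frames (default 3000, i.e. 300 s at 0.1 s).
#' @param regime Sensing regime of the synthetic session.
#' @param seed Integer seed; a fixed seed reproduces the session bit-for-bit.
#' @param dt Frame interval, seconds.
#' @param init_position Initial latent position (arena origin by default).
#' @param init_heading Initial heading, radians, or `NULL` to draw it
#'   uniformly on `(-pi, pi]` from the session stream.
#' @return A list of class `ethosim_gencfg`.
#' @export
generator_config <- function(length = 3000L, regime = "LoS", seed = 1L,
                             dt = 0.1, init_position = c(0, 0),
                             init_heading = NULL) {
  stopifnot(length >= 1, dt > 0, length(init_position) == 2)
  structure(list(length = as.integer(length), regime = match_regime(regime),
                 seed = as.integer(seed), dt = dt,
                 init_position = as.numeric(init_position),
                 init_heading = init_heading),
            class = "ethosim_gencfg")
}

#' Generate a run-based state sequence
#'
#' Draws the first run state from the stationary distribution of the
#' calibrated run-level chain, successive run states from the chain, and run
#' durations by bootstrap resampling from the empirical dwell-time sets; the
#' final run is truncated so the sequence lands exactly on `T` frames.
#'
#' @param chain An `ethosim_calibrated` chain (or any list with `P_alpha` and
#'   `mu`).
#' @param dwell An `ethosim_dwell` with samples for every state.
#' @param T Target length in frames.
#' @return Integer label vector of length `T`.
#' @export
generate_state_sequence <- function(chain, dwell, T) {
  stopifnot(T >= 1, inherits(dwell, "ethosim_dwell"))
  if (any(dwell$absent))
    stop("dwell samples missing for some state", call. = FALSE)
  P <- chain$P_alpha
  cum <- t(apply(P, 1, cumsum))
  states <- integer(0)
  durations <- integer(0)
  s <- findInterval(stats::runif(1), cumsum(chain$mu)) + 1L
  total <- 0L
  while (total < T) {
    ds <- dwell$samples[[s]]
    d <- ds[sample.int(length(ds), 1)]
    states <- c(states, s)
    durations <- c(durations, as.integer(d))
    total <- total + as.integer(d)
    if (total >= T) break
    s <- findInterval(stats::runif(1), cum[s, ]) + 1L
  }
  durations[length(durations)] <- durations[length(durations)] - (total - T)
  rep(states, durations)
}

#' Remove singleton feeding runs from a state sequence
#'
#' Isolated single-frame feeding events (a feeding frame whose neighbors are
#' both non-feeding) are artifacts of run-based synthesis; each is reassigned
#' to the neighboring state whose run is longer, ties resolved in favor of
#' the preceding run. First/last frames are left untouched (the rule needs
#' both neighbors). All other frames are unchanged.
#'
#' @param labels Integer label sequence.
#' @return Smoothed label sequence of equal length.
#' @export
smooth_feeding <- function(labels) {
  labels <- check_labels(labels)
  r <- rle(labels)
  k <- length(r$values)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (r$values[j] == 2L && r$lengths[j] == 1L) {
        r$values[j] <- if (r$lengths[j + 1] > r$lengths[j - 1])
          r$values[j + 1] else r$values[j - 1]
      }
    }
  }
  rep(r$values, r$lengths)
}

#' Synthesize one sensor-observed session
#'
#' Full generative sweep: a run-based state sequence is drawn from the
#' calibrated semi-Markov layer and smoothed; state-conditioned step lengths
#' and turning angles are bootstrap-sampled from the kinematic priors,
#' Winsorized at the state caps, and integrated into a latent trajectory; and
#' per-frame observation distortions for the session's (state, regime) bins
#' are sampled from the channel, magnitude-capped, and added to the latent
#' positions. All randomness flows through one stream seeded from
#' `cfg$seed`, so a fixed seed reproduces the session bit-for-bit.
#'
#' @param bundle A calibrated `ethosim_bundle`.
#' @param cfg An `ethosim_gencfg`.
#' @return An `ethosim_session` with `latent_xy` filled.
#' @export
synthesize_session <- function(bundle, cfg) {
  stopifnot(inherits(bundle, "ethosim_bundle"), inherits(cfg, "ethosim_gencfg"))
  if (is.null(bundle$channel$caps))
    stop("bundle channel has no distortion caps", call. = FALSE)
  set.seed(cfg$seed)
  T <- cfg$length
  labels <- generate_state_sequence(bundle$semi_markov$calibrated,
                                    bundle$semi_markov$dwell, T)
  labels <- smooth_feeding(labels)
  phi1 <- if (is.null(cfg$init_heading)) stats::runif(1, -pi, pi)
          else cfg$init_heading
  latent <- matrix(0, T, 2)
  latent[1, ] <- cfg$init_position
  if (T >= 2) {
    inc <- draw_increments(bundle$priors, labels[-1])
    capped <- cap_increment(inc$l, inc$theta, bundle$priors, labels[-1])
    phi <- phi1 + cumsum(capped$theta)
    latent[-1, 1] <- cfg$init_position[1] + cumsum(capped$l * cos(phi))
    latent[-1, 2] <- cfg$init_position[2] + cumsum(capped$l * sin(phi))
  }
  e <- matrix(0, T, 2)
  for (i in STATES) {
    idx <- which(labels == i)
    if (length(idx) == 0) next
    ei <- sample_distortion(bundle$channel, i, cfg$regime, length(idx))
    cap <- bundle$channel$caps[[bin_key(i, cfg$regime)]]
    e[idx, ] <- cap_distortion(ei, cap)
  }
  session(latent + e, labels, cfg$regime, dt = cfg$dt, latent_xy = latent)
}

# bootstrap draws of (step, turn) conditioned on arrival state; vectorized
# over the frames of each state, one rng call block per state in fixed order
draw_increments <- function(priors, arrival_states) {
  n <- length(arrival_states)
  l <- numeric(n)
  theta <- numeric(n)
  for (i in STATES) {
    idx <- which(arrival_states == i)
    if (length(idx) == 0) next
    Ls <- priors$step_samples[[i]]
    Ts <- priors$turn_samples[[i]]
    if (length(Ls) == 0 || length(Ts) == 0)
      stop("kinematic priors empty for state ", i, call. = FALSE)
    l[idx] <- Ls[sample.int(length(Ls), length(idx), replace = TRUE)]
    theta[idx] <- Ts[sample.int(length(Ts), length(idx), replace = TRUE)]
  }
  list(l = l, theta = theta)
}

#' Synthesize a seeded ensemble of sessions
#'
#' Per-session seed is `base_seed + index`, giving reproducible cohorts whose
#' sessions are independent streams.
#'
#' @param bundle A calibrated `ethosim_bundle`.
#' @param n Number of sessions.
#' @param regime Sensing regime for all sessions.
#' @param base_seed Base seed.
#' @param length Session length, frames.
#' @param dt Frame interval, seconds.
#' @return List of `ethosim_session`.
#' @export
synthesize_ensemble <- function(bundle, n, regime, base_seed,
                                length = 3000L, dt = 0.1) {
  lapply(seq_len(n), function(k)
    synthesize_session(bundle, generator_config(length = length,
                                                regime = regime,
                                                seed = base_seed + k,
                                                dt = dt)))
}
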