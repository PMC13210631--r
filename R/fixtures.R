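#' Default synthetic ground truth for "real-like" sessions
#'
#' A fully specified generative truth standing in for real UWB recordings, so
#' calibration, parameter recovery, and the full pipeline can be exercised
#' against known parameters. The defaults emulate a mouse in an open arena at
#' 10 Hz: exploring dominates through long dwell times and the longest steps;
#' feeding is sparse with short runs and near-stationary motion; burrowing is
#' intermediate. The NLoS channel has a larger bias, wider Gaussian core, and
#' a higher heavy-tail outlier probability than LoS, matching the qualitative
#' asymmetry of UWB propagation.
#'
#' @return An `ethosim_truth` object: `chain` (zero-diagonal transition
#'   matrix), `dwell_law`, `step_law`, `turn_law` (per-state parametric
#'   laws), `channel_truth` (per state and regime), and `occupancy_truth`
#'   implied by the chain and mean dwell times.
#' @export
default_ground_truth <- function() {
  chain <- rbind(c(0, 0.55, 0.45),
                 c(0.85, 0, 0.15),
                 c(0.80, 0.20, 0))
  # dwell = 1 + NegBin(size, mu = mean - 1), frames at 0.1 s
  dwell_law <- list(
    exploring = list(mean = 120, size = 2),
    feeding = list(mean = 15, size = 2),
    burrowing = list(mean = 40, size = 2))
  # per-frame step lengths, meters (gamma); exploring ~ 0.08 m/s, the pace of
  # a caged mouse, slow enough that the reference smoother can track motion
  step_law <- list(
    exploring = list(shape = 2, mean = 0.008),
    feeding = list(shape = 1.5, mean = 0.002),
    burrowing = list(shape = 1.5, mean = 0.004))
  # turning angles: wrapped centered normal, radians; heading is persistent
  # while exploring and near-isotropic during stationary behaviors
  turn_law <- list(
    exploring = list(sd = 0.1),
    feeding = list(sd = 1.5),
    burrowing = list(sd = 1.0))
  ch <- function(mu, sd_g, rho, sd_t) list(
    mu = mu, sigma = diag(2) * sd_g^2, rho = rho,
    lambda = diag(2) * sd_t^2, nu = 4)
  los <- ch(c(0.003, -0.002), 0.015, 0.04, 0.04)
  nlos <- ch(c(0.040, 0.020), 0.035, 0.15, 0.10)
  channel_truth <- list()
  for (i in STATES) {
    channel_truth[[bin_key(i, "LoS")]] <- los
    channel_truth[[bin_key(i, "NLoS")]] <- nlos
  }
  m <- vapply(dwell_law, `[[`, numeric(1), "mean")
  mu <- stationary_distribution(chain)
  structure(list(chain = chain, dwell_law = dwell_law, step_law = step_law,
                 turn_law = turn_law, channel_truth = channel_truth,
                 occupancy_truth = induced_occupancy(mu, unname(m))),
            class = "ethosim_truth")
}

draw_truth_dwell <- function(law, n) {
  1 + stats::rnbinom(n, size = law$size, mu = law$mean - 1)
}

draw_truth_state_sequence <- function(truth, T) {
  mu <- stationary_distribution(truth$chain)
  chain <- list(P_alpha = truth$chain, mu = mu)
  cum <- t(apply(truth$chain, 1, cumsum))
  states <- integer(0); durations <- integer(0)
  s <- findInterval(stats::runif(1), cumsum(mu)) + 1L
  total <- 0L
  while (total < T) {
    d <- as.integer(draw_truth_dwell(truth$dwell_law[[s]], 1))
    states <- c(states, s); durations <- c(durations, d)
    total <- total + d
    if (total >= T) break
    s <- findInterval(stats::runif(1), cum[s, ]) + 1L
  }
  durations[length(durations)] <- durations[length(durations)] - (total - T)
  rep(states, durations)
}

#' Generate ground-truth "real-like" sessions
#'
#' Sessions are generated by the same mechanism the model assumes: semi-Markov
#' states with the truth's parametric dwell laws, state-conditioned gamma step
#' lengths and wrapped-normal turning angles, and additive channel distortion
#' drawn from the truth's per-regime mixture. Latent positions are retained
#' for oracle checks. All randomness flows through one stream seeded once.
#'
#' @param truth An `ethosim_truth`.
#' @param n_los,n_nlos Session counts per regime.
#' @param T Frames per session.
#' @param seed Integer seed.
#' @param dt Frame interval, seconds.
#' @return List of `ethosim_session` with `latent_xy` set.
#' @export
make_real_like_sessions <- function(truth = default_ground_truth(),
                                    n_los = 2, n_nlos = 2, T = 3000L,
                                    seed = 1L, dt = 0.1) {
  stopifnot(inherits(truth, "ethosim_truth"), T >= 2)
  set.seed(seed)
  regimes <- c(rep("LoS", n_los), rep("NLoS", n_nlos))
  lapply(regimes, function(regime) make_truth_session(truth, regime, T, dt))
}

make_truth_session <- function(truth, regime, T, dt) {
  labels <- draw_truth_state_sequence(truth, T)
  arrive <- labels[-1]
  l <- numeric(T - 1); th <- numeric(T - 1)
  for (i in STATES) {
    idx <- which(arrive == i)
    if (!length(idx)) next
    sl <- truth$step_law[[i]]
    l[idx] <- stats::rgamma(length(idx), shape = sl$shape,
                            scale = sl$mean / sl$shape)
    th[idx] <- wrap_angle(stats::rnorm(length(idx), 0, truth$turn_law[[i]]$sd))
  }
  phi <- stats::runif(1, -pi, pi) + cumsum(th)
  latent <- rbind(c(0, 0),
                  cbind(cumsum(l * cos(phi)), cumsum(l * sin(phi))))
  e <- matrix(0, T, 2)
  for (i in STATES) {
    idx <- which(labels == i)
    if (!length(idx)) next
    p <- truth$channel_truth[[bin_key(i, regime)]]
    n <- length(idx)
    is_t <- stats::runif(n) < p$rho
    z <- matrix(stats::rnorm(2 * n), n, 2)
    u <- matrix(0, n, 2)
    if (any(!is_t)) u[!is_t, ] <- z[!is_t, , drop = FALSE] %*% chol(p$sigma)
    if (any(is_t)) {
      wchi <- stats::rchisq(sum(is_t), df = p$nu)
      u[is_t, ] <- (z[is_t, , drop = FALSE] %*% chol(p$lambda)) *
        sqrt(p$nu / wchi)
    }
    e[idx, ] <- sweep(u, 2, p$mu, `+`)
  }
  session(latent + e, labels, regime, dt = dt, latent_xy = latent)
}
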