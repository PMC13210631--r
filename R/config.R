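#' Default run configuration
#'
#' Bundles every fixed constant of the calibration and synthesis pipeline in
#' one place: smoothing windows per sensing regime, Winsorization percentiles,
#' Student-t degrees of freedom, the minimum bin size that triggers
#' hierarchical pooling in the observation channel, histogram bin count and
#' smoothing constant for divergence estimation, the frame interval, the
#' default session length, the occupancy-calibration grid step, and the
#' maximum mean-squared-displacement lag.
#'
#' @param window_los Centered smoothing window under LoS, in samples (odd).
#' @param window_nlos Centered smoothing window under NLoS, in samples (odd).
#' @param p_step Percentile for the state-conditioned step-length cap.
#' @param p_turn Percentile for the state-conditioned turning-angle cap.
#' @param p_dist Percentile for the per-bin observation-distortion cap.
#' @param nu Student-t degrees of freedom of the outlier component (fixed).
#' @param n_min Minimum residual count for a (state, regime) bin before the
#'   channel fit falls back to regime-pooled and then global parameters.
#' @param n_bins Histogram bin count for divergence estimation.
#' @param epsilon Additive smoothing constant for histogram probabilities.
#' @param dt Frame interval in seconds.
#' @param length Default synthetic session length in frames.
#' @param grid_step Grid resolution for occupancy calibration over the
#'   exploring-state outgoing simplex.
#' @param max_lag_s Maximum MSD lag in seconds.
#' @param reg Diagonal regularization (m^2) added to covariance/scale updates
#'   during the channel EM.
#' @return A list of class `ethosim_config`.
#' @export
run_config <- function(window_los = 21L, window_nlos = 41L,
                       p_step = 0.995, p_turn = 0.995, p_dist = 0.999,
                       nu = 4, n_min = 5L, n_bins = 50L, epsilon = 1e-12,
                       dt = 0.1, length = 3000L, grid_step = 0.001,
                       max_lag_s = 30, reg = 1e-9) {
  stopifnot(window_los %% 2 == 1, window_nlos %% 2 == 1,
            p_step > 0, p_step <= 1, p_turn > 0, p_turn <= 1,
            p_dist > 0, p_dist <= 1, nu > 0, n_min >= 1,
            n_bins >= 2, epsilon > 0, dt > 0, length >= 2, grid_step > 0)
  structure(list(
    window_by_regime = c(LoS = as.integer(window_los),
                         NLoS = as.integer(window_nlos)),
    p_step = p_step, p_turn = p_turn, p_dist = p_dist,
    nu = nu, n_min = as.integer(n_min),
    n_bins = as.integer(n_bins), epsilon = epsilon,
    dt = dt, length = as.integer(length),
    grid_step = grid_step, max_lag_s = max_lag_s, reg = reg
  ), class = "ethosim_config")
}

#' Smoothing window for a sensing regime
#' @param config An `ethosim_config`.
#' @param regime `"LoS"` or `"NLoS"`.
#' @return Odd integer window length in samples.
#' @export
regime_window <- function(config, regime) {
  regime <- match_regime(regime)
  config$window_by_regime[[regime]]
}

# canonical state alphabet: 1 exploring, 2 feeding, 3 burrowing
STATES <- 1:3
STATE_NAMES <- c("exploring", "feeding", "burrowing")
REGIMES <- c("LoS", "NLoS")

match_regime <- function(regime) {
  if (length(regime) != 1 || !regime %in% REGIMES)
    stop("regime must be one of 'LoS', 'NLoS'", call. = FALSE)
  regime
}

check_labels <- function(labels) {
  if (length(labels) == 0) stop("empty label sequence", call. = FALSE)
  if (anyNA(labels) || !all(labels %in% STATES))
    stop("labels must lie in the 3-state alphabet {1,2,3}", call. = FALSE)
  as.integer(labels)
}
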