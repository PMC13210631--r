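#' Calibrate a full model bundle from labeled sessions
#'
#' Runs the whole calibration sweep: run segmentation and pooled run-level
#' chain/dwell estimation, occupancy calibration of the exploring-state exits,
#' regime-appropriate reference smoothing, state-conditioned kinematic priors
#' with Winsorization caps, and the EM-fitted observation channel with
#' hierarchical pooling and distortion caps. By default runs and kinematic
#' samples pool across sensing regimes (the observation channel is always
#' regime-conditioned); `per_regime = TRUE` additionally stores per-regime
#' chains and priors, used by the generator when present.
#'
#' @param sessions List of `ethosim_session`.
#' @param config An `ethosim_config`.
#' @param per_regime Also estimate regime-specific dynamics and priors.
#' @return An `ethosim_bundle`.
#' @export
calibrate_model <- function(sessions, config = run_config(),
                            per_regime = FALSE) {
  stopifnot(length(sessions) >= 1,
            all(vapply(sessions, inherits, logical(1), "ethosim_session")))
  runs <- lapply(sessions, function(s) segment_runs(s$labels))
  P_hat <- estimate_transition_matrix(runs)
  dwell <- fit_dwell_model(runs)
  pi_real <- empirical_occupancy(sessions)
  calibrated <- calibrate_occupancy(P_hat, dwell, pi_real,
                                    grid_step = config$grid_step)
  # reference smoothing and per-session priors / residuals
  priors_list <- list()
  res_list <- list()
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    w <- regime_window(config, s$regime)
    ref <- smooth_reference(s$xy, w)
    sessions[[k]]$reference_xy <- ref
    feats <- extract_features(ref)
    priors_list[[k]] <- build_priors(feats, s$labels,
                                     p_step = config$p_step,
                                     p_turn = config$p_turn)
    res_list[[k]] <- list(e = s$xy - ref, states = s$labels,
                          regime = s$regime)
  }
  priors <- merge_priors(priors_list)
  empty <- vapply(priors$step_samples, length, integer(1)) == 0 |
    vapply(priors$turn_samples, length, integer(1)) == 0
  if (any(empty))
    stop("no kinematic samples for state(s): ",
         paste(STATE_NAMES[empty], collapse = ", "),
         "; cannot build a model bundle", call. = FALSE)
  res <- residual_set(
    do.call(rbind, lapply(res_list, `[[`, "e")),
    unlist(lapply(res_list, `[[`, "states")),
    unlist(lapply(res_list, function(r) rep(r$regime, length(r$states)))))
  channel <- fit_channel(res, nu = config$nu, n_min = config$n_min,
                         reg = config$reg)
  caps <- compute_distortion_caps(res, p_dist = config$p_dist,
                                  n_min = config$n_min)
  channel <- set_channel_caps(channel, caps, config$p_dist)
  bundle <- structure(list(
    semi_markov = list(P_hat = P_hat, dwell = dwell, pi_real = pi_real,
                       calibrated = calibrated),
    priors = priors, channel = channel, config = config
  ), class = "ethosim_bundle")
  if (per_regime) {
    by_regime <- list()
    for (c in REGIMES) {
      idx <- vapply(sessions, function(s) s$regime == c, logical(1))
      if (!any(idx)) next
      by_regime[[c]] <- list(
        P_hat = estimate_transition_matrix(runs[idx]),
        dwell = fit_dwell_model(runs[idx]),
        priors = merge_priors(priors_list[idx]),
        pi_real = empirical_occupancy(sessions[idx]))
    }
    bundle$by_regime <- by_regime
  }
  bundle
}
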