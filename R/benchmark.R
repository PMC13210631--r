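#' Perturbation specification for the benchmark's "affected" class
#'
#' The perturbed class applies a mild motion-level perturbation: a random
#' speed reduction drawn from `speed_range`, relabeling of a random fraction
#' (from `relabel_range`) of exploring frames as feeding, and i.i.d. Gaussian
#' positional jitter with a standard deviation drawn from `jitter_range`.
#'
#' @param speed_range Fractional speed reduction range (default 2-12%).
#' @param relabel_range Fraction of exploring frames relabeled as feeding
#'   (default 0.3-1.2%).
#' @param jitter_range Jitter standard deviation range, meters
#'   (default 0.001-0.006).
#' @return A list of class `ethosim_pertspec`.
#' @export
perturbation_spec <- function(speed_range = c(0.02, 0.12),
                              relabel_range = c(0.003, 0.012),
                              jitter_range = c(0.001, 0.006)) {
  stopifnot(length(speed_range) == 2, all(speed_range >= 0), all(speed_range < 1),
            length(relabel_range) == 2, all(relabel_range >= 0),
            all(relabel_range < 1),
            length(jitter_range) == 2, all(jitter_range >= 0))
  structure(list(speed_range = speed_range, relabel_range = relabel_range,
                 jitter_range = jitter_range), class = "ethosim_pertspec")
}

#' Apply the disease-inspired perturbation to a synthetic session
#'
#' The speed reduction rescales latent displacement increments by `1 - u`
#' (positions rebuilt cumulatively) and re-adds the session's original
#' per-frame distortion, because the perturbation targets the motion model,
#' not the sensor; jitter is then added to the observed coordinates.
#' Relabeling flips a uniformly chosen fraction of exploring frames to
#' feeding. Draws come from the current RNG stream.
#'
#' @param s An `ethosim_session` with `latent_xy` present.
#' @param spec An `ethosim_pertspec`.
#' @return The perturbed `ethosim_session`.
#' @export
perturb_session <- function(s, spec = perturbation_spec()) {
  stopifnot(inherits(s, "ethosim_session"), inherits(spec, "ethosim_pertspec"))
  if (is.null(s$latent_xy))
    stop("perturbation requires a session with latent positions", call. = FALSE)
  T <- nrow(s$xy)
  u <- stats::runif(1, spec$speed_range[1], spec$speed_range[2])
  f <- stats::runif(1, spec$relabel_range[1], spec$relabel_range[2])
  jsd <- stats::runif(1, spec$jitter_range[1], spec$jitter_range[2])
  e <- s$xy - s$latent_xy
  d <- diff(s$latent_xy) * (1 - u)
  latent <- rbind(s$latent_xy[1, , drop = FALSE],
                  sweep(apply(d, 2, cumsum), 2, s$latent_xy[1, ], `+`))
  labels <- s$labels
  exploring <- which(labels == 1L)
  if (length(exploring)) {
    n_flip <- round(f * length(exploring))
    if (n_flip > 0) {
      flip <- exploring[sample.int(length(exploring), n_flip)]
      labels[flip] <- 2L
    }
  } else {
    warning("session has no exploring frames; relabeling skipped",
            call. = FALSE)
  }
  jitter <- matrix(stats::rnorm(2 * T, 0, jsd), T, 2)
  session(latent + e + jitter, labels, s$regime, dt = s$dt,
          latent_xy = latent)
}

#' Session-level summary features for the classifier benchmark
#'
#' Deterministic feature vector per session: state occupancy (3); step-length
#' mean/sd/median/95th percentile (meters); mean and sd of absolute turning
#' angle (radians); mean/sd/99th percentile of the proxy-residual magnitude
#' against the regime-appropriate smoother (meters); observed MSD at 1, 5,
#' and 10 s lags (m^2); plus a 0/1 regime indicator iff `sensor_aware`.
#' Kinematics are computed on the observed trajectory.
#'
#' @param s An `ethosim_session` with at least 101 frames.
#' @param sensor_aware Append the sensing-regime indicator.
#' @param config An `ethosim_config` (smoother windows, dt).
#' @return Named numeric vector.
#' @export
extract_session_features <- function(s, sensor_aware = TRUE,
                                     config = run_config()) {
  stopifnot(inherits(s, "ethosim_session"))
  T <- nrow(s$xy)
  lag_frames <- round(c(1, 5, 10) / s$dt)
  if (T < max(lag_frames) + 1)
    stop("session too short for the 10 s MSD descriptor", call. = FALSE)
  occ <- empirical_occupancy(s$labels)
  f <- extract_features(s$xy)
  w <- regime_window(config, s$regime)
  ref <- smooth_reference(s$xy, w)
  rmag <- sqrt(rowSums((s$xy - ref)^2))
  msd_pts <- vapply(lag_frames, function(k) {
    d <- s$xy[(1 + k):T, , drop = FALSE] - s$xy[1:(T - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  out <- c(
    occ_exploring = occ[1], occ_feeding = occ[2], occ_burrowing = occ[3],
    step_mean = mean(f$step), step_sd = stats::sd(f$step),
    step_median = stats::median(f$step),
    step_p95 = unname(stats::quantile(f$step, 0.95, type = 7)),
    turn_absmean = mean(abs(f$turn)), turn_abssd = stats::sd(abs(f$turn)),
    res_mean = mean(rmag), res_sd = stats::sd(rmag),
    res_p99 = unname(stats::quantile(rmag, 0.99, type = 7)),
    msd_1s = msd_pts[1], msd_5s = msd_pts[2], msd_10s = msd_pts[3])
  if (sensor_aware) out <- c(out, regime_nlos = as.numeric(s$regime == "NLoS"))
  out
}

#' Cohort specification for the robustness benchmark
#' @param n_sessions Total cohort size (default 600; half per class).
#' @param length Frames per session.
#' @return A list of class `ethosim_cohortspec`.
#' @export
cohort_spec <- function(n_sessions = 600L, length = 3000L) {
  stopifnot(n_sessions %% 4 == 0, length >= 101)
  structure(list(n_sessions = as.integer(n_sessions),
                 length = as.integer(length)),
            class = "ethosim_cohortspec")
}

BENCH_SETTINGS <- c("sensor_aware_mixed", "sensor_aware_los",
                    "sensor_aware_nlos", "agnostic_los_to_nlos",
                    "agnostic_nlos_to_los")

# plan the (split, class, regime, seed) layout for one benchmark run;
# seeds are base + index, so train and test ranges are disjoint by
# construction and asserted
plan_cohort <- function(setting, n, base_seed) {
  half <- n %/% 2
  split <- rep(c("train", "test"), each = half)
  y <- rep(rep(0:1, each = half %/% 2), times = 2)
  regime <- character(n)
  for (part in c("train", "test")) {
    for (cls in 0:1) {
      idx <- which(split == part & y == cls)
      m <- length(idx)
      regime[idx] <- switch(setting,
        sensor_aware_mixed = rep(REGIMES, length.out = m),
        sensor_aware_los = if (part == "train") rep(REGIMES, length.out = m)
                           else rep("LoS", m),
        sensor_aware_nlos = if (part == "train") rep(REGIMES, length.out = m)
                            else rep("NLoS", m),
        agnostic_los_to_nlos = if (part == "train") rep("LoS", m)
                               else rep("NLoS", m),
        agnostic_nlos_to_los = if (part == "train") rep("NLoS", m)
                               else rep("LoS", m))
    }
  }
  seeds <- base_seed + seq_len(n)
  stopifnot(length(intersect(seeds[split == "train"],
                             seeds[split == "test"])) == 0)
  data.frame(split = split, y = y, regime = regime, seed = seeds,
             stringsAsFactors = FALSE)
}

#' Sensor-aware versus condition-agnostic classifier benchmark
#'
#' Generates a balanced unperturbed-versus-perturbed synthetic cohort from a
#' calibrated bundle, extracts session-level summary features, z-scores them
#' on the training split, fits an L2-regularized logistic regression, and
#' scores the seed-disjoint test split. Sensor-aware settings train on a
#' mixed-regime cohort with the regime indicator as a covariate;
#' condition-agnostic settings train on one regime and test on the other
#' without the indicator, probing LoS/NLoS domain shift. AUC comes from the
#' decision scores; accuracy and balanced accuracy use the fixed 0.5
#' probability threshold.
#'
#' @param bundle A calibrated `ethosim_bundle`.
#' @param setting One of `"sensor_aware_mixed"`, `"sensor_aware_los"`,
#'   `"sensor_aware_nlos"`, `"agnostic_los_to_nlos"`,
#'   `"agnostic_nlos_to_los"`.
#' @param cohort An `ethosim_cohortspec`.
#' @param pert An `ethosim_pertspec`.
#' @param seed Base seed; per-session seed is `seed + index`.
#' @return An `ethosim_benchmark` result: `auc`, `accuracy`,
#'   `balanced_accuracy`, `setting`, `n_train`, `n_test`.
#' @export
run_benchmark <- function(bundle, setting = "sensor_aware_mixed",
                          cohort = cohort_spec(), pert = perturbation_spec(),
                          seed = 1L) {
  stopifnot(inherits(bundle, "ethosim_bundle"),
            setting %in% BENCH_SETTINGS)
  sensor_aware <- startsWith(setting, "sensor_aware")
  plan <- plan_cohort(setting, cohort$n_sessions, seed)
  feats <- matrix(NA_real_, nrow(plan), if (sensor_aware) 16L else 15L)
  for (k in seq_len(nrow(plan))) {
    cfg <- generator_config(length = cohort$length, regime = plan$regime[k],
                            seed = plan$seed[k], dt = bundle$config$dt)
    s <- synthesize_session(bundle, cfg)
    if (plan$y[k] == 1) s <- perturb_session(s, pert)
    feats[k, ] <- extract_session_features(s, sensor_aware = sensor_aware,
                                           config = bundle$config)
  }
  tr <- plan$split == "train"
  if (length(unique(plan$y[tr])) < 2 || length(unique(plan$y[!tr])) < 2)
    stop("degenerate single-class split", call. = FALSE)
  ctr <- colMeans(feats[tr, , drop = FALSE])
  sds <- apply(feats[tr, , drop = FALSE], 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  z <- sweep(sweep(feats, 2, ctr), 2, sds, `/`)
  fit <- glmnet::glmnet(z[tr, , drop = FALSE], factor(plan$y[tr]),
                        family = "binomial", alpha = 0,
                        lambda = 1 / sum(tr), standardize = FALSE,
                        thresh = 1e-10)
  prob <- drop(stats::predict(fit, z[!tr, , drop = FALSE], type = "response"))
  y_test <- plan$y[!tr]
  auc <- as.numeric(pROC::auc(y_test, prob, quiet = TRUE,
                              direction = "<", levels = c(0, 1)))
  pred <- as.integer(prob >= 0.5)
  acc <- mean(pred == y_test)
  recall <- vapply(0:1, function(c) mean(pred[y_test == c] == c), numeric(1))
  structure(list(setting = setting, auc = auc, accuracy = acc,
                 balanced_accuracy = mean(recall),
                 n_train = sum(tr), n_test = sum(!tr), seed = seed),
            class = "ethosim_benchmark")
}

#' @export
print.ethosim_benchmark <- function(x, ...) {
  cat(sprintf("<ethosim_benchmark> %s: AUC %.3f, accuracy %.3f, balanced accuracy %.3f (n=%d/%d)\n",
              x$setting, x$auc, x$accuracy, x$balanced_accuracy,
              x$n_train, x$n_test))
  invisible(x)
}
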