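#' Two-stage reference smoothing (rolling median, then rolling mean)
#'
#' Denoises an observed coordinate series into a reference proxy: a centered
#' rolling median of window `w` removes impulsive outliers, then a centered
#' rolling mean of the same window removes residual jitter. Near the
#' boundaries the window shrinks symmetrically (down to one sample) so the
#' output has the same length as the input and a reference exists at every
#' frame.
#'
#' @param xy Numeric vector, or a T x 2 position matrix smoothed column-wise.
#' @param w Odd positive window length in samples.
#' @return Smoothed object of the same shape.
#' @export
smooth_reference <- function(xy, w) {
  if (w < 1 || w %% 2 == 0) stop("window must be an odd positive integer",
                                 call. = FALSE)
  if (is.matrix(xy)) {
    if (nrow(xy) == 1) return(xy)
    return(apply(xy, 2, smooth_reference, w = w))
  }
  roll_mean(roll_median(as.numeric(xy), w), w)
}

half_widths <- function(n, w) {
  half <- (w - 1) %/% 2
  t <- seq_len(n)
  pmin(half, t - 1L, n - t)
}

roll_median <- function(v, w) {
  n <- length(v)
  if (w == 1 || n == 1) return(v)
  h <- half_widths(n, w)
  out <- if (n >= w) stats::runmed(v, w, endrule = "keep") else v
  # frames whose symmetric window is narrower than w
  fix <- which(h < (w - 1) %/% 2)
  for (t in fix) out[t] <- stats::median(v[(t - h[t]):(t + h[t])])
  as.numeric(out)
}

roll_mean <- function(v, w) {
  n <- length(v)
  if (w == 1 || n == 1) return(v)
  h <- half_widths(n, w)
  cs <- cumsum(c(0, v))
  t <- seq_len(n)
  (cs[t + h + 1] - cs[t - h]) / (2 * h + 1)
}

#' Residual distortion against a reference trajectory
#'
#' @param observed T x 2 observed positions, meters.
#' @param reference T x 2 reference positions, meters.
#' @return T x 2 matrix of residual vectors `observed - reference`.
#' @export
compute_residuals <- function(observed, reference) {
  observed <- as_xy(observed, "observed")
  reference <- as_xy(reference, "reference")
  if (nrow(observed) != nrow(reference))
    stop("observed and reference must have equal length", call. = FALSE)
  observed - reference
}

#' Wrap angles into (-pi, pi]
#' @param a Angles, radians.
#' @return Wrapped angles in `(-pi, pi]`.
#' @export
wrap_angle <- function(a) {
  r <- a - 2 * pi * floor(a / (2 * pi))
  ifelse(r > pi, r - 2 * pi, r)
}

#' Frame-to-frame kinematic features
#'
#' Step length, heading, and turning angle of a planar trajectory. Steps and
#' headings are defined from frame 2 on; turning angles (wrapped heading
#' differences) from frame 3 on.
#'
#' @param xy T x 2 position matrix, meters, T >= 2.
#' @return An `ethosim_features` object: `step` (length T-1, meters, frames
#'   2..T), `heading` (radians, frames 2..T), `turn` (length T-2, radians in
#'   `(-pi, pi]`, frames 3..T), `n_frames`.
#' @export
extract_features <- function(xy) {
  xy <- as_xy(xy, "xy")
  T <- nrow(xy)
  if (T < 2) stop("need T >= 2 frames for kinematic features", call. = FALSE)
  d <- diff(xy)
  step <- sqrt(rowSums(d^2))
  heading <- atan2(d[, 2], d[, 1])
  turn <- if (T >= 3) wrap_angle(diff(heading)) else numeric(0)
  structure(list(step = step, heading = heading, turn = turn, n_frames = T),
            class = "ethosim_features")
}

#' State-conditioned kinematic priors with Winsorization caps
#'
#' Assigns each step length and turning angle to the behavioral state of its
#' arrival frame, yielding per-state empirical sample sets, and computes
#' high-percentile caps: the `p_step` quantile of each state's step lengths
#' and the `p_turn` quantile of each state's absolute turning angles
#' (type-7 quantiles).
#'
#' @param features An `ethosim_features` object (typically from the smoothed
#'   reference trajectory).
#' @param labels Frame-level labels aligned with the trajectory the features
#'   came from.
#' @param p_step,p_turn Cap percentiles.
#' @return An `ethosim_priors` object: `step_samples`, `turn_samples`,
#'   `abs_turn_samples` (lists of 3), `step_cap`, `turn_cap`, percentiles.
#'   States with no samples carry empty sets and `NA` caps.
#' @export
build_priors <- function(features, labels, p_step = 0.995, p_turn = 0.995) {
  stopifnot(inherits(features, "ethosim_features"))
  labels <- check_labels(labels)
  if (length(labels) != features$n_frames)
    stop("labels must align with the feature frames", call. = FALSE)
  step_state <- labels[-1]                       # arrival frames 2..T
  turn_state <- if (features$n_frames >= 3) labels[-(1:2)] else integer(0)
  step_samples <- lapply(STATES, function(i) features$step[step_state == i])
  turn_samples <- lapply(STATES, function(i) features$turn[turn_state == i])
  abs_turn <- lapply(turn_samples, abs)
  qcap <- function(s, p) if (length(s)) unname(stats::quantile(s, p, type = 7))
                         else NA_real_
  structure(list(
    step_samples = step_samples, turn_samples = turn_samples,
    abs_turn_samples = abs_turn,
    step_cap = vapply(step_samples, qcap, numeric(1), p = p_step),
    turn_cap = vapply(abs_turn, qcap, numeric(1), p = p_turn),
    p_step = p_step, p_turn = p_turn
  ), class = "ethosim_priors")
}

#' Merge priors built from several sessions
#' @param priors_list List of `ethosim_priors` built with equal percentiles.
#' @return Pooled `ethosim_priors` with caps recomputed on the merged sets.
#' @export
merge_priors <- function(priors_list) {
  stopifnot(length(priors_list) >= 1)
  p_step <- priors_list[[1]]$p_step
  p_turn <- priors_list[[1]]$p_turn
  pool <- function(field)
    lapply(STATES, function(i)
      unlist(lapply(priors_list, function(p) p[[field]][[i]])))
  step_samples <- pool("step_samples")
  turn_samples <- pool("turn_samples")
  abs_turn <- lapply(turn_samples, abs)
  qcap <- function(s, p) if (length(s)) unname(stats::quantile(s, p, type = 7))
                         else NA_real_
  structure(list(
    step_samples = step_samples, turn_samples = turn_samples,
    abs_turn_samples = abs_turn,
    step_cap = vapply(step_samples, qcap, numeric(1), p = p_step),
    turn_cap = vapply(abs_turn, qcap, numeric(1), p = p_turn),
    p_step = p_step, p_turn = p_turn
  ), class = "ethosim_priors")
}

#' Winsorize a sampled kinematic increment
#'
#' Caps the step length at the state's step cap and the turning-angle
#' magnitude at the state's turn cap, preserving the turn sign. Idempotent.
#'
#' @param l Step length(s), meters.
#' @param theta Turning angle(s), radians.
#' @param priors An `ethosim_priors` with caps for `state`.
#' @param state Arrival-state id (scalar or vector recycled against `l`).
#' @return List with capped `l` and `theta`.
#' @export
cap_increment <- function(l, theta, priors, state) {
  stopifnot(inherits(priors, "ethosim_priors"))
  ql <- priors$step_cap[state]
  qt <- priors$turn_cap[state]
  if (anyNA(ql) || anyNA(qt))
    stop("priors are missing caps for the requested state", call. = FALSE)
  list(l = pmin(l, ql), theta = sign(theta) * pmin(abs(theta), qt))
}
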