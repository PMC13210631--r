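#' Histogram specification for divergence estimation
#' @param n_bins Number of bins (default 50).
#' @param range Length-2 numeric `(lo, hi)` or `NULL` to take it from data.
#' @param epsilon Additive smoothing constant.
#' @return A list of class `ethosim_histspec`.
#' @export
histogram_spec <- function(n_bins = 50L, range = NULL, epsilon = 1e-12) {
  stopifnot(n_bins >= 2, epsilon > 0)
  if (!is.null(range)) stopifnot(length(range) == 2, range[2] > range[1])
  structure(list(n_bins = as.integer(n_bins), range = range,
                 epsilon = epsilon), class = "ethosim_histspec")
}

#' Smoothed histogram probability mass function
#'
#' Bins samples over the spec's range (out-of-range samples are clipped into
#' the edge bins), adds `epsilon` to every count, and normalizes. An empty
#' sample set yields the uniform all-epsilon pmf with a `empty` attribute and
#' a warning.
#'
#' @param samples Numeric samples.
#' @param spec An `ethosim_histspec` with a non-null range.
#' @return Probability vector of length `n_bins` summing to 1.
#' @export
histogram_pmf <- function(samples, spec) {
  stopifnot(inherits(spec, "ethosim_histspec"), !is.null(spec$range))
  B <- spec$n_bins
  if (length(samples) == 0) {
    warning("empty sample set; returning uniform pmf", call. = FALSE)
    return(structure(rep(1 / B, B), empty = TRUE))
  }
  lo <- spec$range[1]; hi <- spec$range[2]
  edges <- seq(lo, hi, length.out = B + 1)
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), B)
  counts <- tabulate(idx, nbins = B)
  p <- (counts + spec$epsilon) / sum(counts + spec$epsilon)
  p
}

#' Kullback-Leibler divergence between two pmfs (nats)
#' @param p,q Strictly positive probability vectors of equal length.
#' @return `sum(p * log(p / q))`, nonnegative, zero iff `p == q`.
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q))
    stop("pmfs must have equal length", call. = FALSE)
  stopifnot(all(p > 0), all(q > 0))
  sum(p * log(p / q))
}

two_sample_ks <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) return(NA_real_)
  unname(suppressWarnings(stats::ks.test(x, y)$statistic))
}

# pooled per-state features of a set of sessions, computed on the observed
# trajectory with arrival-state conditioning
pooled_state_features <- function(sessions) {
  step <- vector("list", 3); turn <- vector("list", 3)
  for (s in sessions) {
    f <- extract_features(s$xy)
    zstep <- s$labels[-1]
    zturn <- s$labels[-(1:2)]
    for (i in STATES) {
      step[[i]] <- c(step[[i]], f$step[zstep == i])
      turn[[i]] <- c(turn[[i]], f$turn[zturn == i])
    }
  }
  list(step = step, turn = turn)
}

pooled_residual_mags <- function(sessions, config) {
  unlist(lapply(sessions, function(s) {
    w <- regime_window(config, s$regime)
    ref <- smooth_reference(s$xy, w)
    sqrt(rowSums((s$xy - ref)^2))
  }))
}

#' Statistical Turing report: real versus synthetic sessions
#'
#' Compares a synthetic session set against a real one under the same sensing
#' regime: per-state occupancy error, state-conditioned KL divergence of step
#' lengths and turning angles (shared histogram edges over the pooled range
#' of both sources), an occupancy-weighted KL summary, and KL plus the
#' two-sample Kolmogorov-Smirnov statistic on residual magnitudes pooled
#' across states. Features are taken from the observed trajectories; residual
#' magnitudes use the regime-appropriate reference smoother.
#'
#' @param real,synth Lists of `ethosim_session`, all under one regime.
#' @param spec An `ethosim_histspec` (range is derived per feature).
#' @param pi_real Reference occupancy weights; defaults to the empirical
#'   occupancy of `real`.
#' @param config An `ethosim_config` (smoothing windows for residuals).
#' @return An `ethosim_turing` report.
#' @export
turing_report <- function(real, synth, spec = histogram_spec(),
                          pi_real = NULL, config = run_config()) {
  stopifnot(length(real) >= 1, length(synth) >= 1)
  regimes <- unique(c(vapply(real, `[[`, character(1), "regime"),
                      vapply(synth, `[[`, character(1), "regime")))
  if (length(regimes) != 1)
    stop("real and synthetic sessions must share one sensing regime",
         call. = FALSE)
  if (is.null(pi_real)) pi_real <- empirical_occupancy(real)
  pi_synth <- rowMeans(vapply(synth, function(s) empirical_occupancy(s$labels),
                              numeric(3)))
  fr <- pooled_state_features(real)
  fs <- pooled_state_features(synth)
  kl <- matrix(NA_real_, 3, 2, dimnames = list(STATE_NAMES, c("step", "turn")))
  for (feat in c("step", "turn")) {
    all_samples <- c(unlist(fr[[feat]]), unlist(fs[[feat]]))
    rng <- range(all_samples)
    if (rng[2] <= rng[1]) rng[2] <- rng[1] + 1e-12
    sp <- histogram_spec(spec$n_bins, rng, spec$epsilon)
    for (i in STATES) {
      p <- suppressWarnings(histogram_pmf(fr[[feat]][[i]], sp))
      q <- suppressWarnings(histogram_pmf(fs[[feat]][[i]], sp))
      kl[i, feat] <- kl_divergence(p, q)
    }
  }
  wkl <- drop(pi_real %*% kl)
  rr <- pooled_residual_mags(real, config)
  rs <- pooled_residual_mags(synth, config)
  rrng <- range(c(rr, rs))
  if (rrng[2] <= rrng[1]) rrng[2] <- rrng[1] + 1e-12
  rsp <- histogram_spec(spec$n_bins, rrng, spec$epsilon)
  residual_kl <- kl_divergence(suppressWarnings(histogram_pmf(rr, rsp)),
                               suppressWarnings(histogram_pmf(rs, rsp)))
  residual_ks <- two_sample_ks(rr, rs)
  structure(list(
    regime = regimes,
    occupancy_error = pi_synth - pi_real,
    kl_by_state = kl,
    weighted_kl = wkl,
    residual_kl = residual_kl,
    residual_ks = residual_ks,
    pi_real = pi_real, pi_synth = pi_synth
  ), class = "ethosim_turing")
}

#' @export
print.ethosim_turing <- function(x, ...) {
  cat(sprintf("<ethosim_turing> regime %s\n", x$regime))
  cat("  occupancy error:",
      paste(sprintf("%+.4f", x$occupancy_error), collapse = " "), "\n")
  cat(sprintf("  weighted KL: step %.4f, turn %.4f nats\n",
              x$weighted_kl[1], x$weighted_kl[2]))
  cat(sprintf("  residual KL %.4f nats, residual KS %.4f\n",
              x$residual_kl, x$residual_ks))
  invisible(x)
}

#' Mean-squared displacement curve
#'
#' `MSD(k) = mean over t of ||x[t+k] - x[t]||^2` for lags `k = 1..K` frames.
#'
#' @param xy T x 2 position matrix, meters.
#' @param K Maximum lag in frames, `K < T`.
#' @param dt Frame interval, seconds.
#' @return An `ethosim_msd` object: `lags` (frames), `tau` (seconds), `msd`
#'   (m^2), `n_pairs`.
#' @export
msd <- function(xy, K, dt = 0.1) {
  xy <- as_xy(xy, "xy")
  T <- nrow(xy)
  if (K >= T || K < 1) stop("need T > K >= 1", call. = FALSE)
  vals <- vapply(seq_len(K), function(k) {
    d <- xy[(1 + k):T, , drop = FALSE] - xy[1:(T - k), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  structure(list(lags = seq_len(K), tau = seq_len(K) * dt, msd = vals,
                 n_pairs = T - seq_len(K)),
            class = "ethosim_msd")
}

#' Mean MSD curve over a session set
#' @param sessions List of `ethosim_session`.
#' @param K Maximum lag, frames; sessions shorter than `K + 1` are dropped
#'   with a warning.
#' @param use_latent Compute on latent rather than observed positions.
#' @return An `ethosim_msd` with the across-session mean curve and `sd`.
#' @export
mean_msd <- function(sessions, K = 300L, use_latent = FALSE) {
  keep <- vapply(sessions, function(s) nrow(s$xy) > K, logical(1))
  if (!all(keep)) warning(sum(!keep), " session(s) shorter than K+1 excluded",
                          call. = FALSE)
  sessions <- sessions[keep]
  stopifnot(length(sessions) >= 1)
  curves <- vapply(sessions, function(s) {
    xy <- if (use_latent) s$latent_xy else s$xy
    msd(xy, K, s$dt)$msd
  }, numeric(K))
  curves <- matrix(curves, nrow = K)
  structure(list(lags = seq_len(K), tau = seq_len(K) * sessions[[1]]$dt,
                 msd = rowMeans(curves),
                 sd = apply(curves, 1, stats::sd),
                 n_pairs = NULL),
            class = "ethosim_msd")
}

#' RMSE between two mean MSD curves
#' @param curve_real,curve_synth `ethosim_msd` objects on identical lag grids.
#' @return Root-mean-square difference, m^2.
#' @export
rmse_msd <- function(curve_real, curve_synth) {
  if (length(curve_real$lags) != length(curve_synth$lags) ||
      any(curve_real$lags != curve_synth$lags))
    stop("MSD curves must share the same lag grid", call. = FALSE)
  sqrt(mean((curve_synth$msd - curve_real$msd)^2))
}
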