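# shared fixtures, built once per test run

.ethosim_cache <- new.env()

# the standard study-shaped fixture: 2 LoS + 2 NLoS sessions of 3000 frames,
# plus the bundle calibrated on them
cached_real_sessions <- function() {
  if (is.null(.ethosim_cache$real))
    .ethosim_cache$real <- make_real_like_sessions(default_ground_truth(),
                                                   n_los = 2, n_nlos = 2,
                                                   T = 3000, seed = 7)
  .ethosim_cache$real
}

cached_bundle <- function() {
  if (is.null(.ethosim_cache$bundle))
    .ethosim_cache$bundle <- calibrate_model(cached_real_sessions())
  .ethosim_cache$bundle
}

# brute-force two-stage smoother: windowed median then windowed mean with
# symmetric shrink at the boundaries (independent of the package path)
oracle_smooth <- function(v, w) {
  n <- length(v)
  half <- (w - 1) %/% 2
  win_stat <- function(x, fun) {
    out <- numeric(n)
    for (t in seq_len(n)) {
      h <- min(half, t - 1, n - t)
      out[t] <- fun(x[(t - h):(t + h)])
    }
    out
  }
  win_stat(win_stat(v, stats::median), mean)
}

# type-7 quantile by explicit order-statistic interpolation
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# direct-count histogram with edge clipping
oracle_hist_counts <- function(samples, lo, hi, B) {
  edges <- seq(lo, hi, length.out = B + 1)
  counts <- integer(B)
  for (s in samples) {
    b <- which(s <= edges[-1])[1]
    if (is.na(b)) b <- B
    counts[b] <- counts[b] + 1L
  }
  counts
}

# direct evaluation of the MSD sum
oracle_msd <- function(xy, K) {
  T <- nrow(xy)
  vapply(seq_len(K), function(k) {
    acc <- 0
    for (t in 1:(T - k)) acc <- acc + sum((xy[t + k, ] - xy[t, ])^2)
    acc / (T - k)
  }, numeric(1))
}

# residuals simulated straight from the observation model (no smoothing)
simulate_channel_residuals <- function(n, mu, sd_g, rho, sd_t, nu = 4) {
  is_t <- stats::runif(n) < rho
  e <- matrix(stats::rnorm(2 * n, 0, sd_g), n, 2)
  n_t <- sum(is_t)
  if (n_t > 0)
    e[is_t, ] <- matrix(stats::rnorm(2 * n_t, 0, sd_t), n_t, 2) /
      sqrt(stats::rchisq(n_t, nu) / nu)
  sweep(e, 2, mu, `+`)
}
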