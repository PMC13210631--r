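test_that("histogram pmfs normalize, clip, and match direct counting", {
  spec <- histogram_spec(10, c(0, 1), 1e-12)
  p <- histogram_pmf(rep(0.55, 100), spec)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_gt(p[6], 0.999)
  expect_true(all(p > 0))

  set.seed(25)
  x <- rnorm(500, 0.5, 0.4)          # some samples fall outside [0, 1]
  p2 <- histogram_pmf(x, spec)
  counts <- oracle_hist_counts(x, 0, 1, 10)
  expect_equal(p2, (counts + 1e-12) / sum(counts + 1e-12), tolerance = 1e-12)
  expect_equal(sum(p2), 1, tolerance = 1e-12)

  expect_warning(pe <- histogram_pmf(numeric(0), spec), "empty")
  expect_equal(unclass(pe), rep(0.1, 10), ignore_attr = TRUE)
})

test_that("KL divergence is exact on hand-computed cases and nonnegative", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log(1.5) + 0.25 * log(0.5), tolerance = 1e-12)
  expect_equal(0.75 * log(1.5) + 0.25 * log(0.5), 0.1308, tolerance = 1e-4)

  set.seed(26)
  for (k in 1:1000) {
    p <- runif(8) + 1e-6; p <- p / sum(p)
    q <- runif(8) + 1e-6; q <- q / sum(q)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)), "equal length")
})

test_that("comparing a session set against itself yields a null Turing report", {
  real <- Filter(function(s) s$regime == "LoS", cached_real_sessions())
  tr <- turing_report(real, real)
  expect_equal(tr$occupancy_error, rep(0, 3))
  expect_equal(max(abs(tr$kl_by_state)), 0, tolerance = 1e-12)
  expect_equal(unname(tr$weighted_kl), c(0, 0), tolerance = 1e-12)
  expect_equal(tr$residual_kl, 0, tolerance = 1e-12)
  expect_equal(tr$residual_ks, 0)
  expect_equal(sum(tr$occupancy_error), 0)
})

test_that("occupancy-weighted KL stays within the per-state extremes", {
  b <- cached_bundle()
  real <- Filter(function(s) s$regime == "NLoS", cached_real_sessions())
  synth <- synthesize_ensemble(b, 4, "NLoS", base_seed = 500, length = 1500)
  tr <- turing_report(real, synth, pi_real = b$semi_markov$pi_real)
  for (j in 1:2) {
    expect_lte(tr$weighted_kl[j], max(tr$kl_by_state[, j]) + 1e-12)
    expect_gte(tr$weighted_kl[j], min(tr$kl_by_state[, j]) - 1e-12)
  }
  expect_error(turing_report(real, Filter(function(s) s$regime == "LoS",
                                          cached_real_sessions())),
               "regime")
})

test_that("two-sample KS under the null stays below its critical value", {
  set.seed(27)
  n <- 400
  crit99 <- 1.63 * sqrt(2 * n / n^2)   # asymptotic 99% two-sample critical value
  hits <- 0
  for (k in 1:100) {
    x <- rnorm(n); y <- rnorm(n)
    d <- unname(suppressWarnings(stats::ks.test(x, y)$statistic))
    if (d < crit99) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("MSD follows its closed forms and the direct-sum oracle", {
  still <- matrix(1.5, 40, 2)
  expect_equal(msd(still, 10)$msd, rep(0, 10))

  # ballistic: straight line with step 0.01 m gives MSD(k) = (0.01 k)^2
  line <- cbind(seq(0, by = 0.01, length.out = 200), rep(0, 200))
  m <- msd(line, 50)
  expect_equal(m$msd, (0.01 * (1:50))^2, tolerance = 1e-12)
  expect_equal(m$n_pairs, 200 - (1:50))

  set.seed(28)
  xy <- matrix(cumsum(rnorm(120)), 60, 2)
  expect_equal(msd(xy, 20)$msd, oracle_msd(xy, 20), tolerance = 1e-12)
  expect_error(msd(xy, 60), "T > K")

  # diffusive: Gaussian walk with per-axis step sd sigma has mean
  # MSD(k) = 2 sigma^2 k
  sigma <- 0.05
  K <- 20
  curves <- replicate(100, {
    xy <- cbind(cumsum(rnorm(400, 0, sigma)), cumsum(rnorm(400, 0, sigma)))
    msd(xy, K)$msd
  })
  avg <- rowMeans(curves)
  se <- apply(curves, 1, stats::sd) / sqrt(100)
  expect_true(all(abs(avg - 2 * sigma^2 * (1:K)) < 3 * se + 1e-12))
})

test_that("MSD-curve RMSE matches its closed forms and direct evaluation", {
  b <- cached_bundle()
  real <- Filter(function(s) s$regime == "LoS", cached_real_sessions())
  m1 <- mean_msd(real, 100)
  expect_equal(rmse_msd(m1, m1), 0)

  m2 <- m1
  m2$msd <- m1$msd + 0.042
  expect_equal(rmse_msd(m1, m2), 0.042, tolerance = 1e-12)

  set.seed(29)
  m3 <- m1
  m3$msd <- m1$msd + rnorm(100, 0, 0.01)
  expect_equal(rmse_msd(m1, m3), sqrt(mean((m3$msd - m1$msd)^2)),
               tolerance = 1e-12)
  m4 <- m1
  m4$lags <- m1$lags[1:50]
  m4$msd <- m1$msd[1:50]
  expect_error(rmse_msd(m1, m4), "lag grid")
})
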