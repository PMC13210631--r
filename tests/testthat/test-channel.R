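test_that("EM recovers pure-Gaussian residuals with a near-zero outlier weight", {
  set.seed(15)
  n <- 20000
  mu <- c(0.01, -0.005); sd_g <- 0.02
  rs <- residual_set(simulate_channel_residuals(n, mu, sd_g, 0, 0.05),
                     rep(1L, n), "LoS")
  ch <- fit_channel(rs)
  p <- ch$bins[["1.LoS"]]
  expect_lt(p$rho, 0.05)
  expect_lt(max(abs(p$mu - mu)), 3 * sd_g / sqrt(n) * 3)
  expect_equal(p$pooling_level, "state_regime")
})

test_that("EM recovers the full mixture with monotone log-likelihood", {
  set.seed(16)
  n <- 20000
  mu <- c(0.05, -0.02); rho <- 0.15
  rs <- residual_set(simulate_channel_residuals(n, mu, 0.02, rho, 0.05),
                     rep(2L, n), "NLoS")
  ch <- fit_channel(rs)
  p <- ch$bins[["2.NLoS"]]
  expect_lt(abs(p$rho - rho), 0.03)
  expect_lt(sqrt(sum((p$mu - mu)^2)), 0.002)
  ll <- p$loglik
  expect_true(all(diff(ll) >= -1e-9 * (abs(ll[-length(ll)]) + 1)))
  # fitted matrices stay symmetric positive-definite
  for (m in list(p$sigma, p$lambda)) {
    expect_equal(m, t(m))
    expect_true(all(eigen(m, symmetric = TRUE)$values > 0))
  }
})

test_that("sparse bins fall back through the pooling chain", {
  set.seed(17)
  e <- simulate_channel_residuals(203, c(0, 0), 0.02, 0.1, 0.05)
  states <- c(rep(1L, 100), rep(2L, 3), rep(1L, 100))
  regimes <- c(rep("LoS", 100), rep("NLoS", 103))
  ch <- fit_channel(residual_set(e, states, regimes), n_min = 5)
  expect_equal(ch$bins[["2.NLoS"]]$pooling_level, "regime")
  expect_equal(ch$bins[["1.LoS"]]$pooling_level, "state_regime")
  # a bin with no samples at all still resolves
  expect_equal(ch$bins[["3.LoS"]]$pooling_level, "regime")
  p <- channel_params(ch, 3, "NLoS")
  expect_true(p$pooling_level %in% c("regime", "global"))

  expect_error(fit_channel(residual_set(e[1:3, ], states[1:3], "LoS"),
                           n_min = 5), "n_min")
})

test_that("distortion sampling matches its model and is seed-deterministic", {
  set.seed(18)
  n <- 20000
  rs <- residual_set(simulate_channel_residuals(n, c(0.01, 0.02), 0.02, 0, 0.05),
                     rep(1L, n), "LoS")
  ch <- fit_channel(rs)
  p <- ch$bins[["1.LoS"]]

  set.seed(181)
  draws <- sample_distortion(ch, 1, "LoS", 1e5)
  sds <- sqrt(diag(p$sigma))
  expect_lt(abs(mean(draws[, 1]) - p$mu[1]), 4 * sds[1] / sqrt(1e5))
  expect_lt(abs(mean(draws[, 2]) - p$mu[2]), 4 * sds[2] / sqrt(1e5))

  # heavy-tail component: pure-t magnitudes have excess kurtosis over Gaussian
  cht <- ch
  cht$bins[["1.LoS"]]$rho <- 1 - 1e-12
  chg <- ch
  chg$bins[["1.LoS"]]$rho <- 0
  set.seed(182)
  mt <- rowSums(sample_distortion(cht, 1, "LoS", 2e4)^2)
  set.seed(183)
  mg <- rowSums(sample_distortion(chg, 1, "LoS", 2e4)^2)
  kurt <- function(x) mean((x - mean(x))^4) / stats::var(x)^2
  expect_gt(kurt(mt), kurt(mg) + 3)

  set.seed(99)
  a <- sample_distortion(ch, 1, "LoS", 50)
  set.seed(99)
  b <- sample_distortion(ch, 1, "LoS", 50)
  expect_identical(a, b)
})

test_that("distortion caps are bin quantiles with pooled fallback", {
  set.seed(19)
  n <- 400
  e <- matrix(rnorm(2 * n, 0, 0.02), n, 2)
  states <- sample(1:3, n, replace = TRUE)
  regimes <- sample(c("LoS", "NLoS"), n, replace = TRUE)
  rs <- residual_set(e, states, regimes)
  caps <- compute_distortion_caps(rs, p_dist = 0.9)
  for (c in c("LoS", "NLoS")) for (i in 1:3) {
    mags <- rs$magnitudes[states == i & regimes == c]
    if (length(mags) >= 5)
      expect_equal(caps[[paste0(i, ".", c)]], oracle_quantile7(mags, 0.9),
                   tolerance = 1e-12)
  }

  # degenerate and boundary quantiles
  req <- residual_set(matrix(rep(c(3, 4) / 1000, each = 6), 6, 2),
                      rep(1L, 6), "LoS")
  ce <- compute_distortion_caps(req, p_dist = 0.999)
  expect_equal(ce[["1.LoS"]], 0.005, tolerance = 1e-12)
  c1 <- compute_distortion_caps(rs, p_dist = 1.0)
  expect_equal(c1[["1.LoS"]],
               max(rs$magnitudes[states == 1 & regimes == "LoS"]))
})

test_that("magnitude capping preserves direction and never exceeds the cap", {
  expect_equal(cap_distortion(c(0.1, 0.2), 1), c(0.1, 0.2))
  expect_equal(cap_distortion(c(3, 4), 1), c(0.6, 0.8))
  e <- matrix(rnorm(200, 0, 2), 100, 2)
  once <- cap_distortion(e, 0.5)
  expect_equal(cap_distortion(once, 0.5), once)
  expect_true(all(sqrt(rowSums(once^2)) <= 0.5 + 1e-12))
  expect_equal(cap_distortion(c(0, 0), 0.5), c(0, 0))

  # capped sampling respects the bound across many draws
  set.seed(20)
  draws <- cap_distortion(matrix(rnorm(2e5, 0, 3), 1e5, 2), 0.25)
  expect_lte(max(sqrt(rowSums(draws^2))), 0.25 * (1 + 1e-12))
})
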