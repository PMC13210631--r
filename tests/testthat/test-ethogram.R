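test_that("run segmentation inverts exactly and conserves total frames", {
  expect_equal(segment_runs(c(1, 1, 1))$states, 1L)
  expect_equal(segment_runs(c(1, 1, 1))$durations, 3L)
  r <- segment_runs(c(1, 2, 1, 2))
  expect_equal(r$states, c(1L, 2L, 1L, 2L))
  expect_equal(r$durations, rep(1L, 4))
  expect_error(segment_runs(c(1, 5)), "alphabet")

  set.seed(11)
  for (k in 1:5) {
    z <- sample(1:3, 1000, replace = TRUE)
    r <- segment_runs(z)
    expect_identical(expand_runs(r), as.integer(z))
    expect_equal(sum(r$durations), r$total_frames)
  }
})

test_that("transition MLE has zero diagonal and handles degenerate rows", {
  r <- segment_runs(c(1, 2, 1, 2, 1))
  tm <- estimate_transition_matrix(r)
  expect_equal(tm$P[1, 2], 1)
  expect_equal(tm$P[2, 1], 1)
  expect_equal(diag(tm$P), rep(0, 3))
  expect_equal(diag(tm$counts), rep(0L, 3))

  # state 3 never exited: uniform fill over the others, flagged
  tm2 <- estimate_transition_matrix(segment_runs(c(1, 2, 1, 2, 3)))
  expect_true(tm2$degenerate[3])
  expect_equal(tm2$P[3, ], c(0.5, 0.5, 0))
  expect_equal(sum(tm2$counts[3, ]), 0)

  expect_error(estimate_transition_matrix(segment_runs(c(1, 1, 1))),
               "no run-level transitions")
})

test_that("transition MLE is Monte-Carlo consistent on a known chain", {
  P <- rbind(c(0, 0.7, 0.3), c(0.2, 0, 0.8), c(0.55, 0.45, 0))
  set.seed(21)
  n <- 1e5
  states <- integer(n)
  states[1] <- 1L
  u <- runif(n)
  cum <- t(apply(P, 1, cumsum))
  for (k in 2:n)
    states[k] <- findInterval(u[k], cum[states[k - 1], ]) + 1L
  runs <- structure(list(states = states, durations = rep(1L, n),
                         total_frames = n), class = "ethosim_runs")
  tm <- estimate_transition_matrix(runs)
  expect_lt(max(abs(tm$P - P)), 0.01)
})

test_that("dwell model stores per-state empirical durations with exact means", {
  r <- structure(list(states = c(1L, 2L, 1L), durations = c(10L, 2L, 6L),
                      total_frames = 18L), class = "ethosim_runs")
  d <- fit_dwell_model(r)
  expect_equal(d$means[1], 8)
  expect_equal(d$means[2], 2)
  expect_true(d$absent[3])
  expect_equal(sort(d$samples[[1]]), c(6, 10))

  # bootstrap draws reproduce the sample mean within 2 standard errors
  set.seed(5)
  pool <- d$samples[[1]]
  draws <- pool[sample.int(length(pool), 1e5, replace = TRUE)]
  se <- stats::sd(pool) / sqrt(1e5) * sqrt((length(pool) - 1) / length(pool))
  expect_lt(abs(mean(draws) - mean(pool)), 2 * stats::sd(pool) / sqrt(1e5) + 4 * se)
})

test_that("stationary distribution solves the fixed point and rejects reducible chains", {
  cyc <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(stationary_distribution(cyc), rep(1 / 3, 3), tolerance = 1e-12)

  set.seed(31)
  for (k in 1:5) {
    P <- matrix(runif(9), 3, 3)
    diag(P) <- 0
    P <- P / rowSums(P)
    mu <- stationary_distribution(P)
    expect_lt(max(abs(drop(mu %*% P) - mu)), 1e-10)
    # power-iteration oracle
    v <- c(1, 0, 0)
    for (j in 1:500) v <- drop(v %*% P)
    expect_equal(mu, v / sum(v), tolerance = 1e-8)
  }

  absorbing <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  expect_error(stationary_distribution(absorbing), "stationary")
})

test_that("induced occupancy weights visitation by mean dwell", {
  expect_equal(induced_occupancy(rep(1 / 3, 3), c(5, 5, 5)), rep(1 / 3, 3))
  pi_v <- induced_occupancy(c(0.5, 0.3, 0.2), c(10, 2, 5))
  expect_equal(pi_v, c(5, 0.6, 1) / 6.6, tolerance = 1e-12)
  expect_equal(sum(pi_v), 1, tolerance = 1e-12)

  # long-run frame-frequency oracle: i.i.d. run states with marginal mu,
  # integer dwells with the target means
  set.seed(41)
  mu <- c(0.5, 0.3, 0.2); m <- c(10, 2, 5)
  s <- sample(1:3, 2e5, replace = TRUE, prob = mu)
  d <- 1 + rpois(2e5, m[s] - 1)
  occ <- vapply(1:3, function(i) sum(d[s == i]), numeric(1)) / sum(d)
  expect_lt(max(abs(occ - pi_v)), 0.005)

  expect_error(induced_occupancy(c(0.5, 0.5, 0), c(1, 0, 1)), "positive")
})

test_that("empirical occupancy counts frames and matches run expansion", {
  expect_equal(empirical_occupancy(c(1, 1, 2, 3)), c(0.5, 0.25, 0.25))
  expect_equal(empirical_occupancy(rep(1, 7)), c(1, 0, 0))
  set.seed(51)
  z <- sample(1:3, 500, replace = TRUE)
  r <- segment_runs(z)
  expect_equal(empirical_occupancy(expand_runs(r)),
               vapply(1:3, function(i) sum(r$durations[r$states == i]),
                      numeric(1)) / r$total_frames)
})

test_that("occupancy calibration recovers known exploring-exit distributions", {
  b <- cached_bundle()
  P_hat <- b$semi_markov$P_hat
  dwell <- b$semi_markov$dwell

  # self-consistency: target built from a known alpha* is recovered on the grid
  alpha_star <- c(0.7, 0.3)
  betas <- b$semi_markov$calibrated$betas
  P_star <- rbind(c(0, alpha_star), betas[1, ], betas[2, ])
  pi_star <- induced_occupancy(stationary_distribution(P_star), dwell)
  cal <- calibrate_occupancy(P_hat, dwell, pi_star, grid_step = 0.001)
  expect_lt(max(abs(cal$alpha - alpha_star)), 0.001 + 1e-12)
  expect_lt(cal$objective, 1e-20)

  # fixed point: the empirical row is recovered when it generates the target
  a_emp <- P_hat$P[1, 2:3] / sum(P_hat$P[1, 2:3])
  P_emp <- rbind(c(0, a_emp), betas[1, ], betas[2, ])
  pi_emp <- induced_occupancy(stationary_distribution(P_emp), dwell)
  cal2 <- calibrate_occupancy(P_hat, dwell, pi_emp, grid_step = 0.001)
  expect_lt(max(abs(cal2$alpha - a_emp)), 0.001 + 1e-12)

  # the reported minimum is global over the grid
  for (a2 in seq(0, 1, by = 0.1)) {
    P <- rbind(c(0, a2, 1 - a2), betas[1, ], betas[2, ])
    mu <- tryCatch(stationary_distribution(P), error = function(e) NULL)
    if (is.null(mu)) next
    obj <- sum((induced_occupancy(mu, dwell) - pi_star)^2)
    expect_gte(obj, cal$objective - 1e-15)
  }
})
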