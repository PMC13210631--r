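test_that("two-stage smoother matches the brute-force windowed oracle", {
  set.seed(8)
  for (w in c(7, 21)) {
    v <- rnorm(100)
    expect_equal(smooth_reference(v, w), oracle_smooth(v, w), tolerance = 1e-12)
  }
  # series shorter than the window: every window shrinks
  v <- rnorm(9)
  expect_equal(smooth_reference(v, 21), oracle_smooth(v, 21), tolerance = 1e-12)

  expect_error(smooth_reference(rnorm(10), 4), "odd")
})

test_that("smoother is constant-preserving, spike-robust, and shift-equivariant", {
  expect_equal(smooth_reference(rep(2.5, 50), 21), rep(2.5, 50))

  v <- rep(1, 100); v[50] <- 1 + 10
  expect_equal(smooth_reference(v, 21), rep(1, 100))

  set.seed(9)
  x <- rnorm(80)
  expect_equal(smooth_reference(x + 3.7, 11), smooth_reference(x, 11) + 3.7,
               tolerance = 1e-12)
})

test_that("residuals are the exact observed-minus-reference difference", {
  set.seed(10)
  ref <- matrix(rnorm(40), 20, 2)
  expect_equal(compute_residuals(ref, ref), matrix(0, 20, 2))
  b <- c(0.3, -0.1)
  obs <- sweep(ref, 2, b, `+`)
  e <- compute_residuals(obs, ref)
  expect_equal(e, matrix(rep(b, each = 20), 20, 2))
  expect_equal(ref + e, obs)
  expect_error(compute_residuals(ref, ref[1:5, ]), "equal length")
})

test_that("kinematic features follow the geometric definitions", {
  # unit steps along +x
  xy <- cbind(0:5, rep(0, 6))
  f <- extract_features(xy)
  expect_equal(f$step, rep(1, 5))
  expect_equal(f$heading, rep(0, 5))
  expect_equal(f$turn, rep(0, 4))

  # right-angle turn
  xy2 <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(extract_features(xy2)$turn, pi / 2)

  expect_error(extract_features(matrix(0, 1, 2)), "T >= 2")
})

test_that("angle wrapping lands in (-pi, pi] and is 2*pi-periodic", {
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  set.seed(12)
  th <- runif(200, -pi, pi)
  for (k in c(-3, -1, 2, 5))
    expect_equal(wrap_angle(th + 2 * pi * k), wrap_angle(th), tolerance = 1e-9)
  w <- wrap_angle(runif(500, -50, 50))
  expect_true(all(w > -pi & w <= pi))
})

test_that("priors condition on the arrival state and partition the samples", {
  set.seed(13)
  xy <- matrix(cumsum(rnorm(60, 0, 0.02)), 30, 2)
  labels <- sample(1:3, 30, replace = TRUE)
  f <- extract_features(xy)
  pr <- build_priors(f, labels)
  expect_equal(sum(lengths(pr$step_samples)), 29)
  expect_equal(sum(lengths(pr$turn_samples)), 28)
  for (i in 1:3)
    expect_equal(pr$step_samples[[i]], f$step[labels[-1] == i])

  # single-state labels leave the other states empty with NA caps
  pr1 <- build_priors(f, rep(1L, 30))
  expect_equal(lengths(pr1$step_samples[2:3]), c(0L, 0L))
  expect_true(all(is.na(pr1$step_cap[2:3])))

  # cap at p = 1 is the sample maximum; caps match the sort-based oracle
  prmax <- build_priors(f, labels, p_step = 1, p_turn = 1)
  for (i in 1:3) {
    if (length(prmax$step_samples[[i]]))
      expect_equal(prmax$step_cap[i], max(prmax$step_samples[[i]]))
  }
  for (i in 1:3) {
    if (length(pr$step_samples[[i]]) > 1)
      expect_equal(pr$step_cap[i],
                   oracle_quantile7(pr$step_samples[[i]], 0.995),
                   tolerance = 1e-12)
    if (length(pr$abs_turn_samples[[i]]) > 1)
      expect_equal(pr$turn_cap[i],
                   oracle_quantile7(pr$abs_turn_samples[[i]], 0.995),
                   tolerance = 1e-12)
  }
})

test_that("increment capping is sign-preserving, contracting, and idempotent", {
  pr <- structure(list(step_cap = c(0.05, 0.02, 0.03),
                       turn_cap = c(2, 1, 1.5),
                       p_step = 0.995, p_turn = 0.995),
                  class = "ethosim_priors")
  c1 <- cap_increment(0.01, 0.5, pr, 1)
  expect_equal(c1$l, 0.01)
  expect_equal(c1$theta, 0.5)

  c2 <- cap_increment(0.1, -3, pr, 1)
  expect_equal(c2$l, 0.05)
  expect_equal(c2$theta, -2)

  c3 <- cap_increment(c2$l, c2$theta, pr, 1)
  expect_equal(c3, c2)

  set.seed(14)
  l <- runif(100, 0, 0.1); th <- runif(100, -pi, pi)
  st <- sample(1:3, 100, replace = TRUE)
  cc <- cap_increment(l, th, pr, st)
  expect_true(all(cc$l <= l + 1e-15))
  expect_true(all(abs(cc$theta) <= abs(th) + 1e-15))
  expect_true(all(sign(cc$theta) == sign(th) | cc$theta == 0))
})
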