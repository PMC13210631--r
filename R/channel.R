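#' Assemble a residual set for observation-channel fitting
#'
#' @param residuals T x 2 matrix of residual vectors, meters.
#' @param states Frame-level state ids aligned with `residuals`.
#' @param regimes Frame-level regimes (`"LoS"`/`"NLoS"`), recycled if scalar.
#' @return An `ethosim_residuals` object with residuals, states, regimes, and
#'   magnitudes.
#' @export
residual_set <- function(residuals, states, regimes) {
  residuals <- as_xy(residuals, "residuals")
  states <- check_labels(states)
  if (length(regimes) == 1) regimes <- rep(regimes, nrow(residuals))
  if (!all(regimes %in% REGIMES)) stop("invalid regime labels", call. = FALSE)
  if (length(states) != nrow(residuals) || length(regimes) != nrow(residuals))
    stop("residuals, states, regimes must be aligned", call. = FALSE)
  structure(list(residuals = residuals, states = states,
                 regimes = as.character(regimes),
                 magnitudes = sqrt(rowSums(residuals^2))),
            class = "ethosim_residuals")
}

bin_key <- function(state, regime) paste0(state, ".", regime)

# log density of a zero-mean bivariate Student-t with scale matrix L, dof nu,
# evaluated at centered points; returns list with logdens and the Mahalanobis
# form needed for the EM weights
mvt_logdens2 <- function(centered, L, nu) {
  ch <- chol(L)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  delta <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  ld <- lgamma((nu + 2) / 2) - lgamma(nu / 2) - log(nu * pi) - logdet / 2 -
    ((nu + 2) / 2) * log1p(delta / nu)
  list(logdens = ld, delta = delta)
}

mvn_logdens2 <- function(centered, S) {
  ch <- chol(S)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  delta <- colSums(z^2)
  logdet <- 2 * sum(log(diag(ch)))
  -log(2 * pi) - logdet / 2 - delta / 2
}

# EM for e = mu + u, u ~ (1 - rho) N(0, Sigma) + rho t_nu(0, Lambda).
# The Student-t is handled through its Gamma scale-mixture augmentation, so
# each iteration is a closed-form ECM sweep and the observed-data
# log-likelihood is non-decreasing.
fit_mixture_em <- function(e, nu = 4, reg = 1e-9, max_iter = 200,
                           tol = 1e-8, rho_init = 0.05) {
  n <- nrow(e)
  mu <- colMeans(e)
  S <- stats::cov(e)
  if (n < 2 || any(!is.finite(S))) S <- diag(2) * 1e-6
  S <- S + diag(2) * reg
  L <- S
  rho <- rho_init
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    centered <- sweep(e, 2, mu)
    lg <- mvn_logdens2(centered, S)
    tt <- mvt_logdens2(centered, L, nu)
    lt <- tt$logdens
    a <- log1p(-rho) + lg
    b <- log(rho) + lt
    m <- pmax(a, b)
    ll <- sum(m + log(exp(a - m) + exp(b - m)))
    ll_trace <- c(ll_trace, ll)
    gamma <- 1 / (1 + exp(a - b))          # responsibility of the t component
    wt <- (nu + 2) / (nu + tt$delta)       # latent scale weight given t
    # location update: precision-weighted over both components
    Sinv <- solve(S)
    Linv <- solve(L)
    g0 <- 1 - gamma
    A <- sum(g0) * Sinv + sum(gamma * wt) * Linv
    bvec <- Sinv %*% colSums(g0 * e) + Linv %*% colSums(gamma * wt * e)
    mu_new <- drop(solve(A, bvec))
    centered <- sweep(e, 2, mu_new)
    S_new <- crossprod(sqrt(g0) * centered) / max(sum(g0), 1e-12) +
      diag(2) * reg
    L_new <- crossprod(sqrt(gamma * wt) * centered) / max(sum(gamma), 1e-12) +
      diag(2) * reg
    rho_new <- min(max(mean(gamma), 1e-4), 1 - 1e-4)
    mu <- mu_new; S <- S_new; L <- L_new; rho <- rho_new
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = S, rho = rho, lambda = L, nu = nu,
       loglik = ll_trace)
}

#' Fit the state- and regime-conditioned observation channel
#'
#' For every (state, regime) bin with at least `n_min` residuals, fits the
#' location-plus-mixture distortion model (Gaussian core with a Student-t
#' outlier component of fixed degrees of freedom) by EM. Sparse bins fall
#' back hierarchically: first to the regime-pooled fit, then to a single
#' global fit, so every bin resolves to parameters.
#'
#' @param res An `ethosim_residuals` object.
#' @param nu Student-t degrees of freedom (fixed, default 4).
#' @param n_min Minimum per-bin sample count before pooling (default 5).
#' @param reg Diagonal regularization for covariance/scale updates, m^2.
#' @return An `ethosim_channel` object: per-bin `bins` (parameters with their
#'   pooling provenance and EM log-likelihood trace), `pooled_regime`,
#'   `pooled_global`, and empty `caps` (see [compute_distortion_caps()]).
#' @export
fit_channel <- function(res, nu = 4, n_min = 5, reg = 1e-9) {
  stopifnot(inherits(res, "ethosim_residuals"))
  e <- res$residuals
  if (!all(is.finite(e))) stop("non-finite residuals", call. = FALSE)
  if (nrow(e) < n_min)
    stop("fewer than n_min residuals in total; cannot fit channel",
         call. = FALSE)
  fit_at <- function(idx, level) {
    f <- fit_mixture_em(e[idx, , drop = FALSE], nu = nu, reg = reg)
    f$pooling_level <- level
    f$n <- length(idx)
    f
  }
  global <- fit_at(seq_len(nrow(e)), "global")
  pooled_regime <- list()
  for (c in REGIMES) {
    idx <- which(res$regimes == c)
    pooled_regime[[c]] <- if (length(idx) >= n_min) fit_at(idx, "regime")
                          else global
  }
  bins <- list()
  for (c in REGIMES) {
    for (i in STATES) {
      idx <- which(res$states == i & res$regimes == c)
      key <- bin_key(i, c)
      bins[[key]] <- if (length(idx) >= n_min) fit_at(idx, "state_regime")
                     else pooled_regime[[c]]
    }
  }
  structure(list(bins = bins, pooled_regime = pooled_regime,
                 pooled_global = global, caps = NULL,
                 cap_percentile = NULL, n_min = n_min, nu = nu),
            class = "ethosim_channel")
}

#' Per-bin distortion-magnitude caps
#'
#' High-percentile caps on residual magnitudes, computed per (state, regime)
#' bin; bins with fewer than `n_min` residuals inherit the regime-pooled cap,
#' then the global cap (the same pooling chain as the channel parameters).
#'
#' @param res An `ethosim_residuals` object.
#' @param p_dist Cap percentile (default 0.999).
#' @param n_min Minimum per-bin count before the cap pools.
#' @return Named numeric vector of caps, meters, keyed `"state.regime"`.
#' @export
compute_distortion_caps <- function(res, p_dist = 0.999, n_min = 5) {
  stopifnot(inherits(res, "ethosim_residuals"))
  if (nrow(res$residuals) == 0)
    stop("empty residual set; cannot compute caps", call. = FALSE)
  r <- res$magnitudes
  qcap <- function(v) unname(stats::quantile(v, p_dist, type = 7))
  global_cap <- qcap(r)
  caps <- c()
  for (c in REGIMES) {
    in_regime <- res$regimes == c
    regime_cap <- if (sum(in_regime) >= n_min) qcap(r[in_regime]) else global_cap
    for (i in STATES) {
      idx <- in_regime & res$states == i
      caps[bin_key(i, c)] <- if (sum(idx) >= n_min) qcap(r[idx]) else regime_cap
    }
  }
  caps
}

#' Attach distortion caps to a fitted channel
#' @param channel An `ethosim_channel`.
#' @param caps Named cap vector from [compute_distortion_caps()].
#' @param p_dist The percentile the caps were computed at.
#' @return The channel with caps attached.
#' @export
set_channel_caps <- function(channel, caps, p_dist) {
  stopifnot(inherits(channel, "ethosim_channel"))
  channel$caps <- caps
  channel$cap_percentile <- p_dist
  channel
}

#' Resolve the parameters for a (state, regime) bin
#' @param channel An `ethosim_channel`.
#' @param state State id.
#' @param regime Sensing regime.
#' @return Parameter list (with its pooling provenance).
#' @export
channel_params <- function(channel, state, regime) {
  stopifnot(inherits(channel, "ethosim_channel"))
  regime <- match_regime(regime)
  p <- channel$bins[[bin_key(check_labels(state), regime)]]
  if (is.null(p)) stop("unresolvable channel bin", call. = FALSE)
  p
}

#' Sample observation distortions
#'
#' Draws `n` distortion vectors for one (state, regime) bin: the bias plus a
#' zero-centered draw from the Gaussian component with probability
#' `1 - rho` or from the Student-t component with probability `rho`. The
#' Student-t is drawn as a Gaussian scale mixture.
#'
#' @param channel An `ethosim_channel`.
#' @param state State id.
#' @param regime Sensing regime.
#' @param n Number of draws.
#' @return n x 2 matrix of distortion vectors, meters.
#' @export
sample_distortion <- function(channel, state, regime, n = 1) {
  p <- channel_params(channel, state, regime)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  is_t <- stats::runif(n) < p$rho
  z <- matrix(stats::rnorm(2 * n), n, 2)
  u <- matrix(0, n, 2)
  n_g <- sum(!is_t)
  if (n_g > 0)
    u[!is_t, ] <- z[!is_t, , drop = FALSE] %*% chol(p$sigma)
  n_t <- sum(is_t)
  if (n_t > 0) {
    wchi <- stats::rchisq(n_t, df = p$nu)
    u[is_t, ] <- (z[is_t, , drop = FALSE] %*% chol(p$lambda)) *
      sqrt(p$nu / wchi)
  }
  sweep(u, 2, p$mu, `+`)
}

#' Cap a distortion vector's magnitude, preserving direction
#'
#' @param e n x 2 matrix (or length-2 vector) of distortion vectors, meters.
#' @param cap Magnitude cap, meters.
#' @return Capped distortions of the same shape.
#' @export
cap_distortion <- function(e, cap) {
  stopifnot(cap > 0)
  vec <- !is.matrix(e)
  if (vec) e <- matrix(e, 1, 2)
  r <- sqrt(rowSums(e^2))
  scale <- ifelse(r > 0, pmin(1, cap / r), 1)
  out <- e * scale
  if (vec) drop(out) else out
}
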