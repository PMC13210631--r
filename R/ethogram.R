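#' Run-length segmentation of a behavioral label sequence
#'
#' Collapses consecutive identical labels into runs. Each run carries a state
#' and a duration in frames; durations sum to the sequence length, so
#' [expand_runs()] inverts the segmentation exactly.
#'
#' @param labels Integer label sequence over the alphabet 1:3.
#' @return An `ethosim_runs` object: `states`, `durations` (frames),
#'   `total_frames`.
#' @export
segment_runs <- function(labels) {
  labels <- check_labels(labels)
  r <- rle(labels)
  structure(list(states = as.integer(r$values),
                 durations = as.integer(r$lengths),
                 total_frames = length(labels)),
            class = "ethosim_runs")
}

#' Expand a run sequence back to frame-level labels
#' @param runs An `ethosim_runs` object.
#' @return Integer label vector of length `total_frames`.
#' @export
expand_runs <- function(runs) {
  stopifnot(inherits(runs, "ethosim_runs"))
  rep(runs$states, runs$durations)
}

as_runs_list <- function(runs) {
  if (inherits(runs, "ethosim_runs")) list(runs)
  else if (is.list(runs) && all(vapply(runs, inherits, logical(1), "ethosim_runs")))
    runs
  else stop("expected an ethosim_runs object or a list of them", call. = FALSE)
}

#' Maximum-likelihood run-level transition matrix
#'
#' Counts run-to-run transitions (pooled across the supplied run sequences),
#' normalizes each row, and forces a zero diagonal: self-transitions are not
#' represented at the run level because persistence is carried by the
#' dwell-time model. A state that is never exited in the data has an undefined
#' row; it is filled uniformly over the other states and flagged degenerate.
#'
#' @param runs An `ethosim_runs` or a list of them.
#' @return An `ethosim_transition` object: `P` (3 x 3, zero diagonal, rows
#'   summing to 1), `counts` (3 x 3 integer), `degenerate` (logical per row).
#' @export
estimate_transition_matrix <- function(runs) {
  runs <- as_runs_list(runs)
  counts <- matrix(0L, 3, 3)
  for (r in runs) {
    s <- r$states
    if (length(s) >= 2) {
      from <- s[-length(s)]; to <- s[-1]
      for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1L
    }
  }
  diag(counts) <- 0L
  if (sum(counts) == 0)
    stop("no run-level transitions observed; cannot estimate chain", call. = FALSE)
  P <- matrix(0, 3, 3)
  degenerate <- logical(3)
  for (i in STATES) {
    tot <- sum(counts[i, ])
    if (tot > 0) {
      P[i, ] <- counts[i, ] / tot
    } else {
      degenerate[i] <- TRUE
      P[i, -i] <- 1 / 2
    }
  }
  structure(list(P = P, counts = counts, degenerate = degenerate),
            class = "ethosim_transition")
}

#' Empirical dwell-time model
#'
#' Collects the observed run durations per state; these multisets are the
#' dwell-time distributions used (by bootstrap resampling) at synthesis time.
#' States with no runs are flagged absent rather than silently pooled.
#'
#' @param runs An `ethosim_runs` or a list of them.
#' @return An `ethosim_dwell` object: `samples` (list of 3 duration vectors,
#'   frames), `means`, `absent`.
#' @export
fit_dwell_model <- function(runs) {
  runs <- as_runs_list(runs)
  states <- unlist(lapply(runs, `[[`, "states"))
  durations <- unlist(lapply(runs, `[[`, "durations"))
  samples <- lapply(STATES, function(i) as.numeric(durations[states == i]))
  means <- vapply(samples, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1))
  structure(list(samples = samples, means = means,
                 absent = vapply(samples, function(s) length(s) == 0, logical(1))),
            class = "ethosim_dwell")
}

#' Stationary distribution of a run-level chain
#'
#' Solves the left eigenproblem of the transition matrix exactly (3 x 3) and
#' validates the result against the defining fixed-point equation. Errors if
#' the unit eigenvalue is not simple or the eigenvector is not nonnegative,
#' i.e. the chain has no unique stationary law.
#'
#' @param P 3 x 3 row-stochastic matrix or an `ethosim_transition`.
#' @return Probability vector `mu` with `mu %*% P == mu` to within 1e-10.
#' @export
stationary_distribution <- function(P) {
  if (inherits(P, "ethosim_transition")) P <- P$P
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(rowSums(P) - 1)) > 1e-8)
    stop("P is not row-stochastic", call. = FALSE)
  e <- eigen(t(P))
  unit <- which(abs(e$values - 1) < 1e-8)
  if (length(unit) != 1)
    stop("chain has no unique stationary distribution", call. = FALSE)
  v <- Re(e$vectors[, unit])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("chain has no unique stationary distribution", call. = FALSE)
  v <- pmax(v, 0)
  mu <- v / sum(v)
  if (max(abs(drop(mu %*% P) - mu)) > 1e-10)
    stop("stationary solve failed to reach fixed point", call. = FALSE)
  mu
}

#' Frame-level occupancy induced by run dynamics
#'
#' Frame occupancy mixes run visitation frequency with mean dwell time:
#' `pi_i = mu_i m_i / sum_l mu_l m_l`.
#'
#' @param mu Stationary run distribution.
#' @param dwell An `ethosim_dwell` or a numeric vector of mean dwell times.
#' @return Occupancy probability vector summing to 1.
#' @export
induced_occupancy <- function(mu, dwell) {
  m <- if (inherits(dwell, "ethosim_dwell")) dwell$means else as.numeric(dwell)
  stopifnot(length(mu) == length(m))
  active <- mu > 0
  if (any(!is.finite(m[active])) || any(m[active] <= 0))
    stop("mean dwell times must be positive for visited states", call. = FALSE)
  w <- mu * ifelse(active, m, 0)
  w / sum(w)
}

#' Empirical frame-level occupancy
#' @param labels Label sequence, an `ethosim_session`, or a list of sessions
#'   (pooled over frames).
#' @return Fraction of frames per state (sums to 1).
#' @export
empirical_occupancy <- function(labels) {
  if (inherits(labels, "ethosim_session")) labels <- labels$labels
  if (is.list(labels))
    labels <- unlist(lapply(labels, function(s)
      if (inherits(s, "ethosim_session")) s$labels else s))
  labels <- check_labels(labels)
  tabulate(labels, nbins = 3) / length(labels)
}

#' Calibrate the dominant-state outgoing distribution to match occupancy
#'
#' The exploring state dominates real sessions through long dwell times, so
#' its few observed run-level exits make the first row of the empirical chain
#' unstable. Calibration replaces that row with `(0, a2, a3)`, `a2 + a3 = 1`,
#' keeps the renormalized empirical structure of the other rows, and picks the
#' `a` whose induced frame occupancy is closest (squared error) to the target
#' occupancy, by exhaustive grid search over the 1-D simplex.
#'
#' @param P_hat An `ethosim_transition` (empirical chain).
#' @param dwell An `ethosim_dwell` with positive means for all three states.
#' @param pi_real Target occupancy probability vector.
#' @param grid_step Grid resolution for `a2` over `[0, 1]`.
#' @return An `ethosim_calibrated` object: `alpha`, `betas` (rows 2-3 of the
#'   template), `P_alpha`, `mu`, `pi_alpha`, `objective`, `grid_step`.
#' @export
calibrate_occupancy <- function(P_hat, dwell, pi_real, grid_step = 0.001) {
  stopifnot(inherits(P_hat, "ethosim_transition"),
            inherits(dwell, "ethosim_dwell"))
  if (abs(sum(pi_real) - 1) > 1e-8 || any(pi_real < 0))
    stop("pi_real must be a probability vector", call. = FALSE)
  if (any(dwell$absent) || any(dwell$means <= 0))
    stop("dwell means must be positive for all states", call. = FALSE)
  betas <- matrix(0, 2, 3)
  for (i in 2:3) {
    off <- P_hat$P[i, ]
    off[i] <- 0
    tot <- sum(off)
    if (tot <= 0)
      stop("row ", i, " of the empirical chain has no off-diagonal mass",
           call. = FALSE)
    betas[i - 1, ] <- off / tot
  }
  grid <- seq(0, 1, by = grid_step)
  best <- NULL
  for (a2 in grid) {
    P <- rbind(c(0, a2, 1 - a2), betas[1, ], betas[2, ])
    mu <- tryCatch(stationary_distribution(P), error = function(e) NULL)
    if (is.null(mu)) next
    pi_a <- induced_occupancy(mu, dwell)
    obj <- sum((pi_a - pi_real)^2)
    if (is.null(best) || obj < best$objective - 1e-15)
      best <- list(alpha = c(a2, 1 - a2), P_alpha = P, mu = mu,
                   pi_alpha = pi_a, objective = obj)
  }
  if (is.null(best))
    stop("all candidate calibrated chains are reducible", call. = FALSE)
  structure(c(best[c("alpha", "P_alpha", "mu", "pi_alpha", "objective")],
              list(betas = betas, grid_step = grid_step)),
            class = "ethosim_calibrated")
}
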