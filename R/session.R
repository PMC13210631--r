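#' Construct a labeled trajectory session
#'
#' A session is one planar trajectory recorded (or synthesized) under a single
#' sensing regime, sampled at a fixed frame interval. Positions are in meters
#' in an arena frame whose origin is (0, 0); behavioral labels take values in
#' the three-state alphabet 1 = exploring, 2 = feeding, 3 = burrowing.
#'
#' @param xy T x 2 numeric matrix of observed positions, meters.
#' @param labels Integer vector of length T with values in 1:3.
#' @param regime `"LoS"` or `"NLoS"`; constant for the whole session.
#' @param dt Frame interval, seconds.
#' @param latent_xy Optional T x 2 matrix of latent (noise-free) positions;
#'   present for synthetic sessions.
#' @param reference_xy Optional T x 2 matrix of smoothed reference positions.
#' @return An object of class `ethosim_session`.
#' @export
session <- function(xy, labels, regime, dt = 0.1,
                    latent_xy = NULL, reference_xy = NULL) {
  xy <- as_xy(xy, "xy")
  labels <- check_labels(labels)
  regime <- match_regime(regime)
  T <- nrow(xy)
  if (T < 2) stop("session must have T >= 2 frames", call. = FALSE)
  if (length(labels) != T)
    stop("labels and positions must have equal length", call. = FALSE)
  if (!is.null(latent_xy)) {
    latent_xy <- as_xy(latent_xy, "latent_xy")
    if (nrow(latent_xy) != T) stop("latent_xy length mismatch", call. = FALSE)
  }
  if (!is.null(reference_xy)) {
    reference_xy <- as_xy(reference_xy, "reference_xy")
    if (nrow(reference_xy) != T) stop("reference_xy length mismatch", call. = FALSE)
  }
  structure(list(
    frame_times = (seq_len(T) - 1) * dt,
    xy = xy, labels = labels, regime = regime, dt = dt,
    latent_xy = latent_xy, reference_xy = reference_xy
  ), class = "ethosim_session")
}

as_xy <- function(m, what) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (ncol(m) != 2) stop(what, " must have two columns", call. = FALSE)
  if (!all(is.finite(m))) stop(what, " contains non-finite positions", call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' @export
print.ethosim_session <- function(x, ...) {
  cat(sprintf("<ethosim_session> %d frames (%.1f s) under %s\n",
              nrow(x$xy), nrow(x$xy) * x$dt, x$regime))
  occ <- empirical_occupancy(x$labels)
  cat(sprintf("  occupancy: exploring %.3f, feeding %.3f, burrowing %.3f\n",
              occ[1], occ[2], occ[3]))
  cat(sprintf("  latent: %s, reference: %s\n",
              if (is.null(x$latent_xy)) "no" else "yes",
              if (is.null(x$reference_xy)) "no" else "yes"))
  invisible(x)
}

#' Read a session from CSV
#'
#' Expects a header `t,x,y,state,regime` with optional `x_lat,y_lat` and
#' `x_ref,y_ref` columns. Time is frame index times the frame interval; the
#' regime column must be constant (`LoS` or `NLoS`).
#'
#' @param path File path.
#' @param dt Frame interval, seconds (time column is validated against it).
#' @return An `ethosim_session`.
#' @export
read_session <- function(path, dt = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "state", "regime")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing session columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) < 2) stop("session must have T >= 2 frames", call. = FALSE)
  regime <- unique(df$regime)
  if (length(regime) != 1)
    stop("regime must be constant within a session", call. = FALSE)
  latent <- if (all(c("x_lat", "y_lat") %in% names(df)))
    cbind(df$x_lat, df$y_lat)
  reference <- if (all(c("x_ref", "y_ref") %in% names(df)))
    cbind(df$x_ref, df$y_ref)
  session(cbind(df$x, df$y), df$state, regime, dt = dt,
          latent_xy = latent, reference_xy = reference)
}

#' Write a session to CSV
#'
#' Numeric fields are written with enough significant digits to round-trip
#' through [read_session()] without loss of analytical precision.
#'
#' @param x An `ethosim_session`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(x, path) {
  stopifnot(inherits(x, "ethosim_session"))
  df <- data.frame(
    t = num_chr(x$frame_times),
    x = num_chr(x$xy[, 1]), y = num_chr(x$xy[, 2]),
    state = x$labels, regime = x$regime,
    stringsAsFactors = FALSE
  )
  if (!is.null(x$latent_xy)) {
    df$x_lat <- num_chr(x$latent_xy[, 1])
    df$y_lat <- num_chr(x$latent_xy[, 2])
  }
  if (!is.null(x$reference_xy)) {
    df$x_ref <- num_chr(x$reference_xy[, 1])
    df$y_ref <- num_chr(x$reference_xy[, 2])
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write session to ", path, call. = FALSE)
  invisible(path)
}

num_chr <- function(v) sprintf("%.12g", v)

#' Serialize a calibrated model bundle to JSON
#'
#' The bundle (semi-Markov layer, kinematic priors, observation channel, and
#' configuration) round-trips losslessly: `save_model` after
#' [load_model()] reproduces the file byte-for-byte because serialization
#' order and numeric formatting are canonical.
#'
#' @param bundle A `ethosim_bundle` from [calibrate_model()].
#' @param path Output path for the JSON file.
#' @return Invisibly, `path`.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "ethosim_bundle"))
  obj <- bundle_to_plain(bundle)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Load a model bundle saved by [save_model()]
#' @param path JSON path.
#' @return A `ethosim_bundle`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(obj$schema_version) || obj$schema_version != BUNDLE_SCHEMA)
    stop("model bundle schema-version mismatch", call. = FALSE)
  plain_to_bundle(obj)
}

BUNDLE_SCHEMA <- "ethosim-bundle-1"

mat_plain <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
plain_mat <- function(l) do.call(rbind, lapply(l, unlist))

params_plain <- function(p) {
  if (is.null(p)) return(NULL)
  list(mu = unname(p$mu), sigma = mat_plain(p$sigma), rho = p$rho,
       lambda = mat_plain(p$lambda), nu = p$nu,
       pooling_level = p$pooling_level, n = p$n)
}
plain_params <- function(p) {
  if (is.null(p)) return(NULL)
  list(mu = unlist(p$mu), sigma = plain_mat(p$sigma), rho = p$rho,
       lambda = plain_mat(p$lambda), nu = p$nu,
       pooling_level = p$pooling_level, n = p$n)
}

bundle_to_plain <- function(b) {
  sm <- b$semi_markov
  pr <- b$priors
  ch <- b$channel
  cl <- sm$calibrated
  list(
    schema_version = BUNDLE_SCHEMA,
    semi_markov = list(
      P_hat = mat_plain(sm$P_hat$P),
      counts = mat_plain(sm$P_hat$counts),
      degenerate = sm$P_hat$degenerate,
      dwell_samples = lapply(sm$dwell$samples, unname),
      dwell_means = unname(sm$dwell$means),
      pi_real = unname(sm$pi_real),
      calibrated = list(
        alpha = unname(cl$alpha),
        betas = mat_plain(cl$betas),
        P_alpha = mat_plain(cl$P_alpha),
        mu = unname(cl$mu),
        pi_alpha = unname(cl$pi_alpha),
        objective = cl$objective,
        grid_step = cl$grid_step
      )
    ),
    priors = list(
      step_samples = lapply(pr$step_samples, unname),
      turn_samples = lapply(pr$turn_samples, unname),
      abs_turn_samples = lapply(pr$abs_turn_samples, unname),
      step_cap = unname(pr$step_cap),
      turn_cap = unname(pr$turn_cap),
      p_step = pr$p_step, p_turn = pr$p_turn
    ),
    channel = list(
      bins = lapply(ch$bins, params_plain),
      pooled_regime = lapply(ch$pooled_regime, params_plain),
      pooled_global = params_plain(ch$pooled_global),
      caps = as.list(ch$caps),
      cap_percentile = ch$cap_percentile,
      n_min = ch$n_min, nu = ch$nu
    ),
    config = unclass(b$config)[c("p_step", "p_turn", "p_dist", "nu", "n_min",
                                 "n_bins", "epsilon", "dt", "length",
                                 "grid_step", "max_lag_s", "reg")] |>
      c(list(window_by_regime = as.list(b$config$window_by_regime)))
  )
}

plain_to_bundle <- function(o) {
  sm <- o$semi_markov
  clo <- sm$calibrated
  cfg <- o$config
  config <- run_config(
    window_los = cfg$window_by_regime$LoS, window_nlos = cfg$window_by_regime$NLoS,
    p_step = cfg$p_step, p_turn = cfg$p_turn, p_dist = cfg$p_dist,
    nu = cfg$nu, n_min = cfg$n_min, n_bins = cfg$n_bins,
    epsilon = cfg$epsilon, dt = cfg$dt, length = cfg$length,
    grid_step = cfg$grid_step, max_lag_s = cfg$max_lag_s, reg = cfg$reg)
  P_hat <- list(P = plain_mat(sm$P_hat), counts = plain_mat(sm$counts),
                degenerate = unlist(sm$degenerate))
  class(P_hat) <- "ethosim_transition"
  dwell <- list(samples = lapply(sm$dwell_samples, unlist0),
                means = vapply(sm$dwell_samples,
                               function(s) if (length(s)) mean(unlist(s)) else NA_real_,
                               numeric(1)),
                absent = vapply(sm$dwell_samples, function(s) length(s) == 0,
                                logical(1)))
  class(dwell) <- "ethosim_dwell"
  calibrated <- list(alpha = unlist(clo$alpha), betas = plain_mat(clo$betas),
                     P_alpha = plain_mat(clo$P_alpha), mu = unlist(clo$mu),
                     pi_alpha = unlist(clo$pi_alpha),
                     objective = clo$objective, grid_step = clo$grid_step)
  class(calibrated) <- "ethosim_calibrated"
  priors <- structure(list(
    step_samples = lapply(o$priors$step_samples, unlist0),
    turn_samples = lapply(o$priors$turn_samples, unlist0),
    abs_turn_samples = lapply(o$priors$abs_turn_samples, unlist0),
    step_cap = unlist(o$priors$step_cap),
    turn_cap = unlist(o$priors$turn_cap),
    p_step = o$priors$p_step, p_turn = o$priors$p_turn
  ), class = "ethosim_priors")
  channel <- structure(list(
    bins = lapply(o$channel$bins, plain_params),
    pooled_regime = lapply(o$channel$pooled_regime, plain_params),
    pooled_global = plain_params(o$channel$pooled_global),
    caps = unlist(o$channel$caps),
    cap_percentile = o$channel$cap_percentile,
    n_min = o$channel$n_min, nu = o$channel$nu
  ), class = "ethosim_channel")
  structure(list(
    semi_markov = list(P_hat = P_hat, dwell = dwell,
                       pi_real = unlist(sm$pi_real), calibrated = calibrated),
    priors = priors, channel = channel, config = config
  ), class = "ethosim_bundle")
}

unlist0 <- function(s) if (length(s)) unlist(s) else numeric(0)

#' @export
print.ethosim_bundle <- function(x, ...) {
  cl <- x$semi_markov$calibrated
  cat("<ethosim_bundle>\n")
  cat(sprintf("  calibrated exploring exits: alpha = (%.3f, %.3f), objective = %.3g\n",
              cl$alpha[1], cl$alpha[2], cl$objective))
  cat(sprintf("  target occupancy: %s\n",
              paste(sprintf("%.3f", x$semi_markov$pi_real), collapse = ", ")))
  cat(sprintf("  channel bins: %s\n", paste(names(x$channel$bins), collapse = ", ")))
  invisible(x)
}
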