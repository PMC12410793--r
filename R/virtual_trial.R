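# Named substreams: each component of a trial (meals, sensor, stress)
# draws from its own deterministic seed derived from the run seed, so
# changing one component never perturbs the others.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Random unannounced meal schedule
#'
#' Sporadic carbohydrate intakes of 1-5 g at 2-4 h intervals: gaps uniform
#' on [120, 240] min, sizes uniform on [1, 5] g. Deterministic for a fixed
#' seed.
#'
#' @param seed integer seed.
#' @param duration trial length (min).
#' @param gap_range,carb_range uniform ranges for the inter-meal gap (min)
#'   and meal size (g).
#' @return data frame of class `meal_schedule` with `time_min` (strictly
#'   increasing) and `carbs_g`.
#' @export
generate_meals <- function(seed, duration,
                           gap_range = c(120, 240), carb_range = c(1, 5)) {
  stopifnot(duration >= 0)
  rng <- local({
    set.seed(substream_seed(seed, "meals"))
    function(n, lo, hi) stats::runif(n, lo, hi)
  })
  times <- numeric(0); carbs <- numeric(0)
  t <- rng(1, gap_range[1], gap_range[2])
  while (t < duration) {
    times <- c(times, t)
    carbs <- c(carbs, rng(1, carb_range[1], carb_range[2]))
    t <- t + rng(1, gap_range[1], gap_range[2])
  }
  structure(data.frame(time_min = times, carbs_g = carbs),
            class = c("meal_schedule", "data.frame"))
}

#' CGM sensor artifact model
#'
#' @param dropout_prob per-sample probability of a missing reading.
#' @param outlier_prob per-sample probability of a spike artifact.
#' @param outlier_mag spike magnitude (mg/dL, sign randomized).
#' @param noise_sd additive Gaussian noise SD (mg/dL).
#' @param quantum sensor quantization step (mg/dL); 0 = off.
#' @return object of class `sensor_model`.
#' @export
sensor_model <- function(dropout_prob = 0.01, outlier_prob = 0.005,
                         outlier_mag = 75, noise_sd = 2, quantum = 1) {
  stopifnot(dropout_prob >= 0, dropout_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1,
            outlier_mag >= 0, noise_sd >= 0, quantum >= 0)
  structure(list(dropout_prob = dropout_prob, outlier_prob = outlier_prob,
                 outlier_mag = outlier_mag, noise_sd = noise_sd,
                 quantum = quantum), class = "sensor_model")
}

#' Corrupt a clean glucose series with sensor artifacts
#'
#' Applies, in order: additive Gaussian noise, spike outliers (random
#' sign), quantization, and dropouts (set to `NA`). Reproducible for a
#' fixed seed via the "sensor" substream.
#'
#' @param clean numeric vector of true glycemia samples (mg/dL).
#' @param sensor a [sensor_model()].
#' @param seed integer seed.
#' @return list: `cgm` (numeric, `NA` at dropouts), `missing` (logical),
#'   `outlier` (logical).
#' @export
corrupt_cgm <- function(clean, sensor = sensor_model(), seed = 1) {
  stopifnot(inherits(sensor, "sensor_model"))
  n <- length(clean)
  set.seed(substream_seed(seed, "sensor"))
  y <- clean
  if (sensor$noise_sd > 0) y <- y + stats::rnorm(n, 0, sensor$noise_sd)
  outlier <- stats::runif(n) < sensor$outlier_prob
  if (any(outlier)) {
    sign <- sample(c(-1, 1), sum(outlier), replace = TRUE)
    y[outlier] <- y[outlier] + sign * sensor$outlier_mag
  }
  if (sensor$quantum > 0) y <- round(y / sensor$quantum) * sensor$quantum
  y <- pmax(y, 1)
  missing <- stats::runif(n) < sensor$dropout_prob
  y[missing] <- NA_real_
  list(cgm = y, missing = missing, outlier = outlier)
}

#' Plant-model mismatch specification
#'
#' Multiplicative perturbation factors applied to the plant's parameters
#' relative to the controller's model (e.g. `p2 = 1.3` inflates the
#' plant's insulin sensitivity by 30%).
#'
#' @param ... named factors among p0..p5 (unnamed parameters keep 1).
#' @return object of class `mismatch_spec` (named numeric of length 6).
#' @export
mismatch_spec <- function(...) {
  fac <- c(p0 = 1, p1 = 1, p2 = 1, p3 = 1, p4 = 1, p5 = 1)
  given <- c(...)
  if (length(given)) {
    if (is.null(names(given)) || !all(names(given) %in% names(fac))) {
      stop("mismatch factors must be named among p0..p5")
    }
    fac[names(given)] <- given
  }
  structure(fac, class = "mismatch_spec")
}

#' Apply a mismatch to a parameter set
#'
#' @param params controller-side [model_parameters()].
#' @param mismatch a [mismatch_spec()].
#' @return perturbed `model_parameters` (validated: must stay positive).
#' @export
apply_mismatch <- function(params, mismatch) {
  p <- as_model_parameters(params)
  fac <- unclass(mismatch)
  as_model_parameters(unclass(p) * fac[names(unclass(p))])
}

#' Run a closed-loop virtual trial
#'
#' Simulates the full loop at a 5-min cadence: a virtual subject (the
#' plant, optionally parameter-perturbed relative to the controller's
#' model) regulated by the offset-free zone MPC, with unannounced meals
#' and CGM artifacts. A 72-h trial at T = 5 min performs exactly 864
#' control cycles. Initial plant glycemia defaults to the post-procedure
#' hyperglycemic 400 mg/dL.
#'
#' @param plant_params the controller's (nominal) parameter set.
#' @param mismatch a [mismatch_spec()] applied to the plant side.
#' @param zone,cfg controller configuration ([zone_spec()],
#'   [controller_config()]).
#' @param dist disturbance model for the estimator.
#' @param meals a [generate_meals()] schedule, or `NULL` for none.
#' @param sensor a [sensor_model()], or `NULL` for a perfect sensor.
#' @param duration trial length (min); default 72 h.
#' @param seed run seed (controls the sensor substream; pass the same seed
#'   used for [generate_meals()] to reproduce a full scenario).
#' @param y0 initial plant glycemia (mg/dL).
#' @param x0 optional full initial plant state (length 5, overrides `y0`),
#'   e.g. an [impulsive_fixed_point()] to start a trial at rest.
#' @param estimator named list of overrides passed to [estimator_init()]
#'   (e.g. `list(q_d = 2, gain = "steady-state")`).
#' @return object of class `closed_loop_trace`: data frame with columns
#'   time_min, glucose_true, cgm, cgm_missing, insulin_U, meal_g,
#'   projection_5min, x2..x5, d_hat, solver_status.
#' @export
run_trial <- function(plant_params, mismatch = mismatch_spec(),
                      zone = zone_spec(), cfg = controller_config(),
                      dist = disturbance_model("input"),
                      meals = NULL, sensor = NULL,
                      duration = 72 * 60, seed = 1, y0 = 400, x0 = NULL,
                      estimator = list()) {
  model_params <- as_model_parameters(plant_params)
  plant_p <- apply_mismatch(model_params, mismatch)
  T <- cfg$T
  n <- as.integer(floor(duration / T))
  imp_model <- discretize(build_continuous(model_params), T)
  imp_plant <- discretize(build_continuous(plant_p), T)
  aug <- augment(imp_model, dist)
  ctrl <- ofzmpc_controller(aug, zone, cfg)

  # meal grams per sample: meal at time t lands in the sample containing t
  meal_per_step <- numeric(n)
  if (!is.null(meals) && nrow(meals)) {
    idx <- pmin(pmax(floor(meals$time_min / T) + 1L, 1L), n)
    for (i in seq_along(idx)) {
      meal_per_step[idx[i]] <- meal_per_step[idx[i]] + meals$carbs_g[i]
    }
  }

  # simulate plant forward while corrupting its CGM on the fly is not
  # possible (the loop is causal), so sensor draws are pre-sampled
  set.seed(substream_seed(seed, "sensor"))
  noise <- stats::rnorm(n, 0, if (is.null(sensor)) 0 else sensor$noise_sd)
  u_out <- if (is.null(sensor)) rep(FALSE, n) else
    stats::runif(n) < sensor$outlier_prob
  out_sign <- sample(c(-1, 1), n, replace = TRUE)
  u_drop <- if (is.null(sensor)) rep(FALSE, n) else
    stats::runif(n) < sensor$dropout_prob

  x <- if (is.null(x0)) c(y0, 0, 0, 0, 0) else as.numeric(x0)
  stopifnot(length(x) == 5L)
  y0 <- x[1]
  est <- NULL
  rows <- vector("list", n)
  projection_prev <- NA_real_
  for (k in seq_len(n)) {
    y <- x[1] + noise[k]
    if (u_out[k]) y <- y + out_sign[k] * sensor$outlier_mag
    if (!is.null(sensor) && sensor$quantum > 0) {
      y <- round(y / sensor$quantum) * sensor$quantum
    }
    y <- max(y, 1)
    if (u_drop[k]) y <- NA_real_
    if (is.null(est)) {
      est <- do.call(estimator_init,
                     c(list(aug = aug, y0 = if (is.na(y)) y0 else y),
                       estimator))
    }
    res <- closed_loop_step(x, est, ctrl, imp_plant, meal_per_step[k],
                            y = y)
    se <- state_estimate(res$est)
    rows[[k]] <- data.frame(
      time_min = (k - 1L) * T,
      glucose_true = x[1],
      cgm = y,
      cgm_missing = is.na(y),
      insulin_U = res$sol$applied,
      meal_g = meal_per_step[k],
      projection_5min = projection_prev,
      x2 = x[2], x3 = x[3], x4 = x[4], x5 = x[5],
      d_hat = se$dhat[1],
      solver_status = res$sol$status)
    projection_prev <- res$projection
    x <- res$plant_x
    est <- res$est
  }
  tr <- do.call(rbind, rows)
  attr(tr, "seed") <- seed
  attr(tr, "params") <- unclass(model_params)
  attr(tr, "mismatch") <- unclass(mismatch)
  class(tr) <- c("closed_loop_trace", "data.frame")
  tr
}
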