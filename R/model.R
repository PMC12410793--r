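#' Continuous five-compartment glucose-insulin model
#'
#' Builds the linear state-space model
#' \deqn{\dot x(t) = A x(t) + B_u u(t) + B_r r(t) + E, \qquad y = C x,}
#' with states x1 glycemia (mg/dL), x2/x3 insulin delivery rates in the
#' blood and subcutaneous compartments (U/min), x4/x5 carbohydrate delivery
#' rates in the gut and stomach (g/min). Insulin (u, U/min) enters the
#' subcutaneous compartment x3 with gain 1/p4; carbohydrates (r, g/min)
#' enter the stomach compartment x5 with gain 1/p5 and reach glycemia
#' through the gut compartment x4 with bioavailability p3.
#'
#' @param params a [model_parameters()] object (or coercible named vector).
#' @return An object of class `continuous_model`: list with `A` (5x5),
#'   `Bu`, `Br`, `E` (5-vectors), `C` (1x5) and the `params` used.
#' @export
build_continuous <- function(params) {
  p <- as_model_parameters(params)
  p0 <- p[["p0"]]; p1 <- p[["p1"]]; p2 <- p[["p2"]]
  p3 <- p[["p3"]]; p4 <- p[["p4"]]; p5 <- p[["p5"]]
  A <- matrix(0, 5, 5)
  A[1, 1] <- -p1
  A[1, 2] <- -p2
  A[1, 4] <- p3
  A[2, 2] <- -1 / p4
  A[2, 3] <- 1 / p4
  A[3, 3] <- -1 / p4
  A[4, 4] <- -1 / p5
  A[4, 5] <- 1 / p5
  A[5, 5] <- -1 / p5
  Bu <- c(0, 0, 1 / p4, 0, 0)
  Br <- c(0, 0, 0, 0, 1 / p5)
  E <- c(p0, 0, 0, 0, 0)
  C <- matrix(c(1, 0, 0, 0, 0), 1, 5)
  structure(list(A = A, Bu = Bu, Br = Br, E = E, C = C, params = p),
            class = "continuous_model")
}

#' Impulsive (sampled-time) representation of the continuous model
#'
#' Exact sampling over an impulse period T:
#' `Ad = expm(A T)`, `Bud = expm(A T) Bu` (the insulin dose acts as an
#' impulse at the sampling instant), `Brd = (int_0^T expm(A s) ds) Br` and
#' `Ed = (int_0^T expm(A s) ds) E` (meal rate and the affine term held over
#' the period). The integral is computed with the augmented block-matrix
#' exponential identity
#' `expm([[A, I], [0, 0]] T) = [[expm(A T), int_0^T expm(A s) ds], [0, I]]`,
#' which is exact and does not require A to be invertible (p1 = 0 makes A
#' singular).
#'
#' @param model a `continuous_model` from [build_continuous()].
#' @param T impulse period in minutes (> 0); 5 min for a standard CGM
#'   cadence.
#' @return An object of class `impulsive_model`: list with `Ad`, `Bud`,
#'   `Brd`, `Ed`, `T`, `C` and `params`.
#' @export
discretize <- function(model, T = 5) {
  stopifnot(inherits(model, "continuous_model"))
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0) {
    stop("impulse period T must be a single positive number")
  }
  n <- nrow(model$A)
  M <- matrix(0, 2 * n, 2 * n)
  M[1:n, 1:n] <- model$A
  M[1:n, (n + 1):(2 * n)] <- diag(n)
  EM <- as.matrix(Matrix::expm(M * T))
  Ad <- EM[1:n, 1:n, drop = FALSE]
  Fint <- EM[1:n, (n + 1):(2 * n), drop = FALSE]  # int_0^T expm(A s) ds
  structure(list(Ad = Ad,
                 Bud = drop(Ad %*% model$Bu),
                 Brd = drop(Fint %*% model$Br),
                 Ed = drop(Fint %*% model$E),
                 T = T, C = model$C, params = model$params),
            class = "impulsive_model")
}

#' Convert between a basal rate and its equivalent periodic bolus
#'
#' The continuous model input u is a delivery rate in U/min; the pump
#' delivers a discrete bolus once per period T. A delta-impulse of weight
#' D (with u in U/min) delivers exactly D units, so the impulse weight in
#' the sampled update *is* the dose: a basal rate u U/min is equivalent
#' to the periodic bolus `D = T * u`. Dose limits (e.g. the 0-1 U pump
#' restriction) apply to D.
#'
#' @param u_rate insulin delivery rate (U/min).
#' @param T impulse period (min).
#' @return equivalent periodic bolus (U).
#' @export
basal_dose <- function(u_rate, T) u_rate * T

#' One impulsive model step
#'
#' Advances the sampled model one period:
#' `x(k+1) = Ad x(k) + Bud u + Brd (r/T) + Ed`, where `u` is the insulin
#' bolus (U) injected impulsively at instant k (the impulse weight equals
#' the dose, which conserves injected units) and `r` the grams of
#' carbohydrate entering the stomach during the period (the rate `r/T`
#' g/min held over the period, which conserves grams).
#'
#' @param imp an `impulsive_model`.
#' @param x state vector (length 5).
#' @param u insulin bolus (U, >= 0).
#' @param r carbohydrate intake over the period (g, >= 0).
#' @return next state vector (length 5).
#' @export
step <- function(imp, x, u = 0, r = 0) {
  stopifnot(inherits(imp, "impulsive_model"), length(x) == 5L)
  if (!is.finite(u) || u < 0) stop("insulin impulse u must be >= 0")
  if (!is.finite(r) || r < 0) stop("meal input r must be >= 0")
  drop(imp$Ad %*% x) + imp$Bud * u + imp$Brd * (r / imp$T) + imp$Ed
}

#' Constant-input rest point of the continuous model
#'
#' The unique equilibrium of the continuous dynamics at a constant insulin
#' rate with no meals: `x* = (y, u*, u*, 0, 0)` with
#' `u* = (p0 - p1 y) / p2` (U/min). Targets above the zero-insulin level
#' `p0/p1` would require a negative insulin rate and are rejected. When
#' p1 = 0 the glycemia compartment is an integrator: the basal rate
#' `u* = p0/p2` holds any target.
#'
#' @param params a [model_parameters()] object.
#' @param y_target desired glycemia (mg/dL).
#' @return list with `x` (length-5 state) and `u_basal` (U/min).
#' @export
continuous_equilibrium <- function(params, y_target) {
  p <- as_model_parameters(params)
  if (!is.finite(y_target) || y_target < 0) {
    stop("y_target must be a non-negative glycemia in mg/dL")
  }
  y_max <- if (p[["p1"]] > 0) p[["p0"]] / p[["p1"]] else Inf
  if (y_target > y_max) {
    stop(sprintf(paste0("y_target = %.6g mg/dL exceeds the zero-insulin ",
                        "equilibrium p0/p1 = %.6g mg/dL (would require a ",
                        "negative insulin rate)"), y_target, y_max))
  }
  u <- (p[["p0"]] - p[["p1"]] * y_target) / p[["p2"]]
  list(x = c(y_target, u, u, 0, 0), u_basal = u)
}

#' Fixed point of the impulsive model under a periodic bolus
#'
#' Solves `x = Ad x + Bud D + Ed` for the state reached by injecting a
#' constant bolus D every period (no meals). Requires `I - Ad` nonsingular
#' (p1 > 0); with p1 = 0 the sampled glycemia compartment integrates and no
#' isolated fixed point exists.
#'
#' @param imp an `impulsive_model`.
#' @param dose_U periodic bolus (U).
#' @return length-5 state vector.
#' @export
impulsive_fixed_point <- function(imp, dose_U = 0) {
  stopifnot(inherits(imp, "impulsive_model"))
  IA <- diag(5) - imp$Ad
  if (abs(det(IA)) < 1e-12) {
    stop("I - Ad is singular (p1 = 0): no isolated impulsive fixed point")
  }
  drop(solve(IA, imp$Bud * dose_U + imp$Ed))
}

#' Simulate the impulsive model over a dose/meal sequence
#'
#' @param imp an `impulsive_model`.
#' @param x0 initial state (length 5).
#' @param u vector of boluses (U), one per period.
#' @param r vector of per-period carbohydrate inputs (g); recycled to the
#'   length of `u` (default all zero).
#' @return matrix with `length(u) + 1` rows (states at k = 0..N), 5 columns.
#' @export
simulate_impulsive <- function(imp, x0, u, r = 0) {
  n <- length(u)
  r <- rep_len(r, n)
  out <- matrix(NA_real_, n + 1L, 5L)
  out[1L, ] <- x0
  x <- x0
  for (k in seq_len(n)) {
    x <- step(imp, x, u[k], r[k])
    out[k + 1L, ] <- x
  }
  out
}
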