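#' Integrating disturbance model
#'
#' Structure of the constant (integrating) disturbance appended to the
#' sampled model: d(k+1) = d(k), entering the state update through `Bd`
#' and/or the output through `Cd`. The default ("input" mode) injects a
#' single disturbance into the glycemia balance, `Bd = (1,0,0,0,0)'`,
#' `Cd = 0`, where unannounced meals and endogenous-production error act;
#' "output" mode uses `Bd = 0`, `Cd = 1` (a CGM bias).
#'
#' @param mode `"input"` or `"output"`, or `"custom"` with explicit
#'   matrices.
#' @param Bd 5 x nd state-injection matrix (custom mode).
#' @param Cd 1 x nd output-injection matrix (custom mode).
#' @return object of class `disturbance_model` with `Bd`, `Cd`, `nd`.
#' @export
disturbance_model <- function(mode = c("input", "output", "custom"),
                              Bd = NULL, Cd = NULL) {
  mode <- match.arg(mode)
  if (mode == "input") {
    Bd <- matrix(c(1, 0, 0, 0, 0), 5, 1); Cd <- matrix(0, 1, 1)
  } else if (mode == "output") {
    Bd <- matrix(0, 5, 1); Cd <- matrix(1, 1, 1)
  } else {
    if (is.null(Bd) && is.null(Cd)) stop("custom mode needs Bd and/or Cd")
    nd <- if (!is.null(Bd)) ncol(as.matrix(Bd)) else ncol(as.matrix(Cd))
    if (is.null(Bd)) Bd <- matrix(0, 5, nd)
    if (is.null(Cd)) Cd <- matrix(0, 1, nd)
    Bd <- as.matrix(Bd); Cd <- as.matrix(Cd)
  }
  nd <- ncol(Bd)
  if (nd < 1L) stop("disturbance dimension nd must be >= 1")
  if (nrow(Cd) != 1L || ncol(Cd) != nd) {
    stop("disturbance matrices have inconsistent dimensions: Bd must be ",
         "nx x nd and Cd 1 x nd")
  }
  if (all(Bd == 0) && all(Cd == 0)) {
    stop("Bd and Cd must not both be zero (disturbance would be invisible)")
  }
  structure(list(Bd = Bd, Cd = Cd, nd = nd, mode = mode),
            class = "disturbance_model")
}

#' Disturbance-augmented sampled model
#'
#' Appends the integrating disturbance to the impulsive model:
#' \deqn{\tilde A_d = \begin{bmatrix} A_d & B_{dd} \\ 0 & I \end{bmatrix},
#'   \quad B_{dd} = e^{AT} B_d = A_d B_d, \quad \tilde C = [C\; C_d],}
#' with the disturbance rows of the input/meal/affine vectors zero.
#'
#' @param imp an [impulsive_model][discretize].
#' @param dist a [disturbance_model()].
#' @return object of class `augmented_model` with `Atil`, `Bud`, `Brd`,
#'   `Ed` (augmented vectors), `Ctil`, `Bdd`, `nd`, `T` and the parts.
#' @export
augment <- function(imp, dist = disturbance_model("input")) {
  stopifnot(inherits(imp, "impulsive_model"),
            inherits(dist, "disturbance_model"))
  nd <- dist$nd
  nx <- nrow(imp$Ad)
  if (nrow(dist$Bd) != nx) {
    stop("disturbance map Bd has ", nrow(dist$Bd), " rows; the model has ",
         nx, " states")
  }
  n <- nx + nd
  Bdd <- imp$Ad %*% dist$Bd
  Atil <- matrix(0, n, n)
  Atil[1:nx, 1:nx] <- imp$Ad
  Atil[1:nx, (nx + 1L):n] <- Bdd
  Atil[(nx + 1L):n, (nx + 1L):n] <- diag(nd)
  Ctil <- cbind(imp$C, dist$Cd)
  structure(list(Atil = Atil,
                 Bud = c(imp$Bud, rep(0, nd)),
                 Brd = c(imp$Brd, rep(0, nd)),
                 Ed = c(imp$Ed, rep(0, nd)),
                 Ctil = Ctil, Bdd = Bdd, nd = nd, T = imp$T,
                 imp = imp, dist = dist),
            class = "augmented_model")
}

#' Observability rank of the augmented pair
#'
#' Rank of the stacked Kalman observability matrix of `(Atil, Ctil)`. The
#' augmented estimator is well posed iff the rank equals 5 + nd.
#'
#' @param aug an [augmented_model][augment].
#' @param tol rank tolerance passed to [qr()].
#' @return list with `rank` and logical `full_rank`.
#' @export
observability_rank <- function(aug, tol = 1e-9) {
  stopifnot(inherits(aug, "augmented_model"))
  n <- nrow(aug$Atil)
  O <- matrix(NA_real_, n, n)
  row <- aug$Ctil
  for (i in seq_len(n)) {
    O[i, ] <- row
    row <- row %*% aug$Atil
  }
  # scale rows to unit norm so rank tolerance is scale-free
  ns <- sqrt(rowSums(O^2))
  ns[ns == 0] <- 1
  r <- qr(O / ns, tol = tol)$rank
  list(rank = r, full_rank = r == n)
}

#' Initialize the augmented state/disturbance estimator
#'
#' Kalman filter on the augmented model. At trial start there is no prior
#' information: the glycemia estimate is set to the first CGM sample, the
#' remaining states and the disturbance to zero, and the covariance is
#' diagonal with a large entry on the disturbance.
#'
#' @param aug an [augmented_model][augment] (must be observable).
#' @param y0 first CGM sample (mg/dL); `NA` allowed (estimate starts at 0).
#' @param q_x process-noise variance on the five physiological states.
#' @param q_d process-noise variance on the disturbance state. The default
#'   is deliberately much larger than `q_x`: the filter is told to trust
#'   the model states and put significant weight on the plant-model
#'   difference d.
#' @param r_y measurement-noise variance of the CGM (mg/dL^2).
#' @param p0_x,p0_d initial covariance on states / disturbance.
#' @param gain `"time-varying"` (covariance recursion each step) or
#'   `"steady-state"` (gain frozen at the Riccati fixed point, reproducible
#'   over long runs).
#' @return object of class `augmented_estimate` with `xhat` (length 5+nd),
#'   `P`, `L` (current gain), noise matrices and bookkeeping.
#' @export
estimator_init <- function(aug, y0 = NA_real_,
                           q_x = 1e-4, q_d = 1, r_y = 25,
                           p0_x = 100, p0_d = 1e3,
                           gain = c("time-varying", "steady-state")) {
  stopifnot(inherits(aug, "augmented_model"))
  gain <- match.arg(gain)
  if (q_x <= 0 || q_d <= 0 || r_y <= 0) {
    stop("noise variances q_x, q_d, r_y must be positive")
  }
  ob <- observability_rank(aug)
  if (!ob$full_rank) {
    stop("augmented model is not observable (rank ", ob$rank, " < ",
         nrow(aug$Atil), "); choose a different disturbance model")
  }
  n <- nrow(aug$Atil); nd <- aug$nd
  Q <- diag(c(rep(q_x, 5), rep(q_d, nd)), n)
  R <- matrix(r_y, 1, 1)
  P <- diag(c(p0_x, rep(1, 4), rep(p0_d, nd)), n)
  xhat <- rep(0, n)
  if (is.finite(y0)) xhat[1] <- y0
  est <- structure(list(aug = aug, xhat = xhat, P = P, Qn = Q, Rn = R,
                        L = NULL, gain = gain, Kss = NULL, k = 0L,
                        last_innovation = NA_real_, corrected = FALSE),
                   class = "augmented_estimate")
  if (gain == "steady-state") {
    ss <- riccati_fixed_point(aug$Atil, aug$Ctil, Q, R)
    est$Kss <- ss$K
    est$P <- ss$P
  }
  est
}

# Discrete-time filtering Riccati iteration to convergence.
# Returns the a-priori covariance fixed point and the filter gain
# K = P C' (C P C' + R)^-1 (measurement-update form).
riccati_fixed_point <- function(A, C, Q, R, tol = 1e-10, max_iter = 10000L) {
  P <- diag(nrow(A)) * 100
  for (i in seq_len(max_iter)) {
    S <- C %*% P %*% t(C) + R
    K <- P %*% t(C) %*% solve(S)
    Pn <- A %*% (P - K %*% C %*% P) %*% t(A) + Q
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(1, max(abs(P)))) {
      P <- Pn
      break
    }
    P <- Pn
  }
  S <- C %*% P %*% t(C) + R
  list(P = P, K = P %*% t(C) %*% solve(S))
}

#' One estimator cycle (measurement correction + model prediction)
#'
#' Implements the predictor-form update
#' `xhat(k+1) = Atil xhat(k) + Bud u + Brd r + Ed + L (y(k) - Ctil xhat(k))`
#' as a correct-then-predict Kalman cycle, with the gain recomputed from
#' the covariance recursion (time-varying mode) or frozen (steady-state
#' mode). A missing CGM sample (`y = NA`) triggers a prediction-only step:
#' no correction is applied and the covariance inflates by the process
#' noise; the returned estimate has `corrected = FALSE`.
#'
#' @param est an `augmented_estimate`.
#' @param y CGM sample (mg/dL) or `NA` for a sensor dropout.
#' @param u insulin bolus applied at instant k (U).
#' @param r carbohydrate input over the period (g); the controller always
#'   passes 0 (meals are unannounced).
#' @return updated `augmented_estimate`; `est$xhat` is the prediction for
#'   k+1, `est$last_innovation` the innovation used (NA on dropout).
#' @export
kalman_step <- function(est, y, u = 0, r = 0) {
  est <- kalman_correct(est, y)
  kalman_predict(est, u, r)
}

#' @rdname kalman_step
#' @export
kalman_correct <- function(est, y) {
  stopifnot(inherits(est, "augmented_estimate"))
  aug <- est$aug
  if (is.na(y)) {
    est$last_innovation <- NA_real_
    est$corrected <- FALSE
    return(est)
  }
  innov <- y - drop(aug$Ctil %*% est$xhat)
  if (est$gain == "steady-state") {
    K <- est$Kss
  } else {
    S <- aug$Ctil %*% est$P %*% t(aug$Ctil) + est$Rn
    K <- est$P %*% t(aug$Ctil) %*% solve(S)
    est$P <- est$P - K %*% aug$Ctil %*% est$P
    est$P <- (est$P + t(est$P)) / 2
  }
  est$xhat <- est$xhat + drop(K) * innov
  est$L <- K
  est$last_innovation <- innov
  est$corrected <- TRUE
  est
}

#' @rdname kalman_step
#' @export
kalman_predict <- function(est, u = 0, r = 0) {
  stopifnot(inherits(est, "augmented_estimate"))
  aug <- est$aug
  est$xhat <- drop(aug$Atil %*% est$xhat) +
    aug$Bud * u + aug$Brd * (r / aug$T) + aug$Ed
  if (est$gain == "time-varying") {
    est$P <- aug$Atil %*% est$P %*% t(aug$Atil) + est$Qn
    est$P <- (est$P + t(est$P)) / 2
  }
  est$k <- est$k + 1L
  est
}

#' @rdname kalman_step
#' @param est an `augmented_estimate`.
#' @export
state_estimate <- function(est) {
  list(xhat = est$xhat[1:5], dhat = est$xhat[-(1:5)])
}
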