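#' Glycemic target zone and input constraints
#'
#' @param y_lo,y_hi target zone bounds for glycemia (mg/dL); default the
#'   90-130 mg/dL controller zone used in the rodent trials.
#' @param u_min,u_max bolus bounds (U); default the 0-1 U pump restriction.
#' @param x_bounds optional per-state box: list with `lower` and `upper`
#'   length-5 vectors (use -Inf/Inf for unconstrained coordinates).
#'   Enforced on the predicted trajectory x(1..Hp). Default none.
#' @return object of class `zone_spec`.
#' @export
zone_spec <- function(y_lo = 90, y_hi = 130, u_min = 0, u_max = 1,
                      x_bounds = NULL) {
  if (!(y_lo < y_hi)) stop("zone requires y_lo < y_hi")
  if (!(u_min >= 0 && u_min < u_max)) stop("need 0 <= u_min < u_max")
  if (!is.null(x_bounds)) {
    stopifnot(is.list(x_bounds),
              length(x_bounds$lower) == 5L, length(x_bounds$upper) == 5L)
  }
  structure(list(y_lo = y_lo, y_hi = y_hi, u_min = u_min, u_max = u_max,
                 x_bounds = x_bounds), class = "zone_spec")
}

#' Zone MPC tuning
#'
#' @param Hp prediction horizon (steps); 100 steps = 500 min at T = 5.
#' @param Hu control horizon (steps, <= Hp); boluses beyond Hu are pinned
#'   to the artificial equilibrium dose ua (move blocking).
#' @param T impulse period (min).
#' @param Q 5x5 state-deviation weight (PSD). Default penalizes the
#'   glycemia deviation only: `diag(1, 0, 0, 0, 0)`.
#' @param R input-deviation weight (> 0), on bolus deviations (u - ua) in
#'   U^2. Default 10: dose deviations are O(0.1-1) U while glycemia
#'   deviations are O(10-100) mg/dL, so regulation is dominated by the
#'   glucose term and R mainly smooths the transient dosing.
#' @param P terminal / zone weight (> 0). The terminal distance cost is
#'   realized as a heavily weighted quadratic penalty on the slack of the
#'   zone membership of the artificial output ya; P is that weight.
#' @param ridge strictly convex regularization added (relative to the
#'   quadratic-term scale) to every decision variable so the QP optimum is
#'   unique.
#' @param quantum pump dose granularity (U); applied boluses are rounded
#'   to this step when > 0. Default 0 (off).
#' @return object of class `controller_config`.
#' @export
controller_config <- function(Hp = 100, Hu = 30, T = 5,
                              Q = diag(c(1, 0, 0, 0, 0)), R = 10, P = 1e4,
                              ridge = 1e-7, quantum = 0) {
  stopifnot(Hp >= 1, Hu >= 1, Hu <= Hp, T > 0, R > 0, P > 0, ridge >= 0)
  Q <- as.matrix(Q)
  stopifnot(nrow(Q) == ncol(Q))
  ev <- eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("Q must be positive semidefinite")
  structure(list(Hp = as.integer(Hp), Hu = as.integer(Hu), T = T,
                 Q = Q, R = R, P = P, ridge = ridge, quantum = quantum),
            class = "controller_config")
}

#' Offset-free zone MPC controller
#'
#' Precomputes the condensed quadratic program of the offset-free zone MPC
#' for a disturbance-augmented impulsive model. Each period the controller
#' solves, over the free boluses `u(0..Hu-1)`, the artificial equilibrium
#' `(xa, ua)` and the zone slacks `(s_lo, s_hi)`:
#'
#' \deqn{\min \sum_{j=0}^{H_p-1} \|x(j)-x_a\|_Q^2 +
#'       \sum_{j=0}^{H_u-1} R\,(u(j)-u_a)^2 + P\,(s_{lo}^2+s_{hi}^2)}
#'
#' subject to the disturbance-corrected dynamics with the disturbance held
#' constant over the horizon, the initial condition from the current
#' estimate, bolus bounds, the hard terminal equality `x(Hp) = xa`, the
#' equilibrium equalities `xa = Ad xa + Bud ua + Bdd dhat + Ed` and
#' `ya = C xa + Cd dhat`, and the softened zone membership
#' `y_lo - s_lo <= ya <= y_hi + s_hi`, `s >= 0`. The first bolus of the
#' optimal sequence is applied.
#'
#' @param aug an [augmented_model][augment] built from the controller's
#'   prediction model.
#' @param zone a [zone_spec()].
#' @param cfg a [controller_config()] (its `T` must match the model's).
#' @return object of class `ofzmpc_controller` holding the precomputed QP
#'   blocks; pass to [build_qp()] / [ofzmpc_step()].
#' @export
ofzmpc_controller <- function(aug, zone = zone_spec(),
                              cfg = controller_config()) {
  stopifnot(inherits(aug, "augmented_model"), inherits(zone, "zone_spec"),
            inherits(cfg, "controller_config"))
  if (abs(aug$T - cfg$T) > 1e-12) {
    stop("controller period cfg$T and model period aug$T differ")
  }
  Hp <- cfg$Hp; Hu <- cfg$Hu
  Ad <- aug$imp$Ad
  BudD <- aug$imp$Bud                  # per-dose (U) impulse map
  nx <- nrow(Ad)
  if (nrow(cfg$Q) != nx) stop("Q dimension does not match the state")
  nz <- Hu + 1L + nx + 2L              # u(0..Hu-1), ua, xa, s_lo, s_hi
  iu <- seq_len(Hu); iua <- Hu + 1L; ixa <- (Hu + 2L):(Hu + 1L + nx)
  isl <- Hu + nx + 2L; ish <- Hu + nx + 3L

  # sensitivities P_j = d x(j) / d z  (x(0) fixed by the estimate)
  Exa <- matrix(0, nx, nz); Exa[, ixa] <- diag(nx)
  Pj <- matrix(0, nx, nz)
  QB <- matrix(0, nx * Hp, nz)         # stacked Q (P_j - Exa), j = 0..Hp-1
  Hdyn <- matrix(0, nz, nz)
  for (j in seq_len(Hp)) {             # fill row block for j-1, then advance
    B <- Pj - Exa
    QBj <- cfg$Q %*% B
    QB[(nx * (j - 1L) + 1L):(nx * j), ] <- QBj
    Hdyn <- Hdyn + crossprod(B, QBj)
    col <- if (j <= Hu) iu[j] else iua
    Pj <- Ad %*% Pj
    Pj[, col] <- Pj[, col] + BudD
  }
  PHp <- Pj                            # sensitivity of x(Hp)

  # input-deviation cost sum R (u_j - ua)^2
  HR <- matrix(0, nz, nz)
  HR[cbind(iu, iu)] <- cfg$R
  HR[iu, iua] <- HR[iua, iu] <- -cfg$R
  HR[iua, iua] <- cfg$R * Hu
  # slack penalty (terminal zone-distance weight)
  Hs <- matrix(0, nz, nz)
  Hs[isl, isl] <- Hs[ish, ish] <- cfg$P

  Hsum <- Hdyn + HR + Hs
  # diagonal equilibration: the quadratic term spans many decades
  # (glucose-squared curvature on the doses vs no curvature at all on
  # xa2..xa5, which only the equality constraints pin down); quadprog
  # needs a well-scaled matrix. The tie-breaking ridge is added in the
  # equilibrated space so it cannot bias any physical variable.
  floor_d <- 1e-8 * max(diag(Hsum))
  scal <- 1 / sqrt(pmax(diag(Hsum), floor_d))
  ridge <- 2 * cfg$ridge

  # equalities: terminal x(Hp) = xa ; equilibrium (I - Ad) xa - BudD ua = w
  Aeq <- matrix(0, 2L * nx, nz)
  Aeq[1:nx, ] <- PHp - Exa
  Aeq[(nx + 1L):(2L * nx), ixa] <- diag(nx) - Ad
  Aeq[(nx + 1L):(2L * nx), iua] <- -BudD
  # With move blocking the free inputs reach x(Hp) only through
  # Ad^(Hp-Hu..Hp-1): fast modes decay below machine precision and the
  # equality block is numerically rank deficient. Row-reduce it once by
  # SVD: keep the directions with sigma > 1e-10 sigma_max as orthonormal
  # rows; the dropped directions have ~zero coefficients for every z, so
  # their residual is fixed and checked at solve time.
  sv <- svd(Aeq)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  Aeq_r <- t(sv$v[, seq_len(r), drop = FALSE])
  Tb <- diag(1 / sv$d[seq_len(r)], r) %*% t(sv$u[, seq_len(r), drop = FALSE])
  Unull <- sv$u[, -seq_len(r), drop = FALSE]

  # inequalities (t(G) z >= g): bolus bounds, zone with slack, slack >= 0
  Cc <- aug$imp$C
  Gi <- matrix(0, 0, nz); gi <- numeric(0)
  add <- function(row, rhs) {
    Gi <<- rbind(Gi, row); gi <<- c(gi, rhs)
  }
  for (i in c(iu, iua)) {
    r1 <- numeric(nz); r1[i] <- 1; add(r1, zone$u_min)
    r2 <- numeric(nz); r2[i] <- -1; add(r2, -zone$u_max)
  }
  zlo <- numeric(nz); zlo[ixa] <- Cc; zlo[isl] <- 1    # ya + s_lo >= y_lo
  zhi <- numeric(nz); zhi[ixa] <- -Cc; zhi[ish] <- 1   # -ya + s_hi >= -y_hi
  add(zlo, NA); add(zhi, NA)                            # rhs set per solve
  izone <- c(length(gi) - 1L, length(gi))
  sl <- numeric(nz); sl[isl] <- 1; add(sl, 0)
  sh <- numeric(nz); sh[ish] <- 1; add(sh, 0)

  # optional state box on the predicted trajectory (rhs depends on c_j)
  xb <- NULL
  if (!is.null(zone$x_bounds)) {
    rows <- list(); meta <- list()
    Pj <- matrix(0, nx, nz)
    for (j in seq_len(Hp)) {
      col <- if (j <= Hu) iu[j] else iua
      Pj <- Ad %*% Pj
      Pj[, col] <- Pj[, col] + BudD
      for (i in seq_len(nx)) {
        lo <- zone$x_bounds$lower[i]; hi <- zone$x_bounds$upper[i]
        if (is.finite(lo)) {
          rows[[length(rows) + 1L]] <- Pj[i, ]
          meta[[length(meta) + 1L]] <- c(j, i, 1, lo)
        }
        if (is.finite(hi)) {
          rows[[length(rows) + 1L]] <- -Pj[i, ]
          meta[[length(meta) + 1L]] <- c(j, i, -1, hi)
        }
      }
    }
    if (length(rows)) {
      xb <- list(G = do.call(rbind, rows),
                 meta = do.call(rbind, meta))
    }
  }

  structure(list(aug = aug, zone = zone, cfg = cfg,
                 nx = nx, nz = nz, iu = iu, iua = iua, ixa = ixa,
                 isl = isl, ish = ish,
                 Hsum = Hsum, ridge = ridge, scal = scal, QB = QB,
                 Aeq = Aeq_r, Tb = Tb, Unull = Unull,
                 Gi = Gi, gi = gi, izone = izone, xb = xb,
                 Ad = Ad, BudD = BudD, Bdd = aug$Bdd, Ed = aug$imp$Ed,
                 Cd = aug$dist$Cd, Cc = Cc),
            class = "ofzmpc_controller")
}

#' Assemble the QP instance for the current estimate
#'
#' Propagates the estimate-dependent affine part of the prediction and
#' returns the concrete quadratic program (quadprog form) for one control
#' period. Construction always succeeds; infeasibility surfaces at
#' [solve_ofzmpc()].
#'
#' @param ctrl an [ofzmpc_controller()].
#' @param xhat current state estimate (length 5).
#' @param dhat current disturbance estimate (length nd).
#' @return list of class `ofzmpc_qp` with `Dmat`, `dvec`, `Amat`, `bvec`,
#'   `meq`, the cost constant, and bookkeeping indices.
#' @export
build_qp <- function(ctrl, xhat, dhat = 0) {
  stopifnot(inherits(ctrl, "ofzmpc_controller"),
            length(xhat) == ctrl$nx)
  cfg <- ctrl$cfg
  Hp <- cfg$Hp
  w <- drop(ctrl$Bdd %*% dhat) + ctrl$Ed
  # affine part c_j of x(j); stacked for j = 0..Hp-1, then c_Hp
  nx <- ctrl$nx
  cvec <- numeric(nx * Hp)
  cj <- as.numeric(xhat)
  const <- 0
  for (j in seq_len(Hp)) {
    cvec[(nx * (j - 1L) + 1L):(nx * j)] <- cj
    const <- const + drop(crossprod(cj, cfg$Q %*% cj))
    cj <- drop(ctrl$Ad %*% cj) + w
  }
  cHp <- cj
  f <- drop(crossprod(ctrl$QB, cvec))
  beq_full <- c(-cHp, w)
  beq <- drop(ctrl$Tb %*% beq_full)
  null_resid <- if (ncol(ctrl$Unull)) {
    max(abs(drop(crossprod(ctrl$Unull, beq_full))))
  } else 0
  gi <- ctrl$gi
  yd <- drop(ctrl$Cd %*% dhat)
  gi[ctrl$izone[1]] <- ctrl$zone$y_lo - yd
  gi[ctrl$izone[2]] <- -(ctrl$zone$y_hi - yd)
  G <- ctrl$Gi
  if (!is.null(ctrl$xb)) {
    # recompute c_j-dependent rhs for the state box rows
    cj <- as.numeric(xhat)
    cmat <- matrix(0, nx, Hp)
    for (j in seq_len(Hp)) {
      cj <- drop(ctrl$Ad %*% cj) + w
      cmat[, j] <- cj
    }
    m <- ctrl$xb$meta
    rhs <- ifelse(m[, 3] > 0,
                  m[, 4] - cmat[cbind(m[, 2], m[, 1])],
                  -(m[, 4] - cmat[cbind(m[, 2], m[, 1])]))
    G <- rbind(G, ctrl$xb$G)
    gi <- c(gi, rhs)
  }
  s <- ctrl$scal
  structure(list(Dmat = outer(s, s) * (2 * ctrl$Hsum) +
                   diag(ctrl$ridge, ctrl$nz),
                 dvec = s * (-2 * f),
                 Amat = s * t(rbind(ctrl$Aeq, G)),
                 bvec = c(beq, gi), meq = nrow(ctrl$Aeq),
                 const = const, f = f, ctrl = ctrl,
                 null_resid = null_resid,
                 xhat = xhat, dhat = dhat),
            class = "ofzmpc_qp")
}

#' Solve the zone MPC quadratic program
#'
#' Dual active-set solve of the instance from [build_qp()]. On any solver
#' failure (infeasible hard constraints, numerical breakdown) the
#' controller fails safe: it returns a zero bolus with status
#' `"failed-safe"` rather than injecting insulin on an unreliable
#' solution. A solution that needed the zone slack (the artificial output
#' cannot be placed inside the zone for the current disturbance estimate)
#' is flagged `"zone-relaxed"`.
#'
#' @param qp an `ofzmpc_qp`.
#' @return object of class `control_solution`: `u_seq` (length Hp, U),
#'   `xa`, `ua`, `ya`, `slack`, `cost` (V_N), `status`, `applied`.
#' @export
solve_ofzmpc <- function(qp) {
  stopifnot(inherits(qp, "ofzmpc_qp"))
  ctrl <- qp$ctrl
  if (qp$null_resid > 1e-4) {
    return(structure(list(u_seq = rep(0, ctrl$cfg$Hp),
                          xa = rep(NA_real_, ctrl$nx), ua = NA_real_,
                          ya = NA_real_, slack = NA_real_, cost = NA_real_,
                          status = "failed-safe", applied = 0,
                          message = "terminal equality numerically infeasible"),
                     class = "control_solution"))
  }
  sol <- tryCatch(
    quadprog::solve.QP(qp$Dmat, qp$dvec, qp$Amat, qp$bvec, meq = qp$meq),
    error = function(e) e)
  if (inherits(sol, "error")) {
    return(structure(list(u_seq = rep(0, ctrl$cfg$Hp),
                          xa = rep(NA_real_, ctrl$nx), ua = NA_real_,
                          ya = NA_real_, slack = NA_real_, cost = NA_real_,
                          status = "failed-safe", applied = 0,
                          message = conditionMessage(sol)),
                     class = "control_solution"))
  }
  z <- ctrl$scal * sol$solution        # undo the equilibration
  zone <- ctrl$zone
  u_free <- pmin(pmax(z[ctrl$iu], zone$u_min), zone$u_max)
  ua <- min(max(z[ctrl$iua], zone$u_min), zone$u_max)
  xa <- z[ctrl$ixa]
  slack <- c(lo = z[ctrl$isl], hi = z[ctrl$ish])
  ya <- drop(ctrl$Cc %*% xa) + drop(ctrl$Cd %*% qp$dhat)
  u_seq <- c(u_free, rep(ua, ctrl$cfg$Hp - ctrl$cfg$Hu))
  cost <- drop(crossprod(z, ctrl$Hsum %*% z)) + 2 * sum(qp$f * z) + qp$const
  applied <- u_seq[1]
  if (ctrl$cfg$quantum > 0) {
    applied <- round(applied / ctrl$cfg$quantum) * ctrl$cfg$quantum
    applied <- min(max(applied, zone$u_min), zone$u_max)
  }
  status <- if (max(slack) > 1e-6) "zone-relaxed" else "optimal"
  structure(list(u_seq = u_seq, xa = xa, ua = ua, ya = ya, slack = slack,
                 cost = cost, status = status, applied = applied),
            class = "control_solution")
}

#' @export
print.control_solution <- function(x, ...) {
  cat(sprintf("OF-ZMPC solution [%s]: applied %.4f U, ua = %.4f U, ya = %.2f mg/dL, V_N = %.4g\n",
              x$status, x$applied, x$ua, x$ya, x$cost))
  invisible(x)
}

#' Convenience: estimate in, applied bolus out
#'
#' @param ctrl an [ofzmpc_controller()].
#' @param xhat,dhat current estimates.
#' @return a `control_solution`.
#' @export
ofzmpc_step <- function(ctrl, xhat, dhat = 0) {
  solve_ofzmpc(build_qp(ctrl, xhat, dhat))
}

#' Dynamic (stage) cost of a candidate trajectory
#'
#' `sum_j ||x(j) - xa||_Q^2 + sum_j ||u(j) - ua||_R^2` with j over the
#' first `length(u_seq)` stages.
#'
#' @param traj matrix of predicted states, rows x(0), x(1), ...; at least
#'   as many rows as `length(u_seq)`.
#' @param u_seq bolus sequence (U).
#' @param xa,ua artificial equilibrium.
#' @param Q,R weights as in [controller_config()].
#' @return scalar cost.
#' @export
dynamic_cost <- function(traj, u_seq, xa, ua, Q = diag(c(1, 0, 0, 0, 0)),
                         R = 10) {
  traj <- as.matrix(traj)
  N <- length(u_seq)
  if (nrow(traj) < N) stop("trajectory shorter than the input sequence")
  dx <- sweep(traj[seq_len(N), , drop = FALSE], 2, xa)
  sum((dx %*% Q) * dx) + R * sum((u_seq - ua)^2)
}

#' Terminal cost: distance of (xa, ua) to the target equilibrium sets
#'
#' `P (dist_Xtar(xa) + dist_Utar(ua))` where the target sets are the
#' equilibria of the disturbance-corrected sampled model whose output lies
#' in the zone and whose dose respects the bolus bounds. Each distance is
#' the Euclidean projection computed by a small QP. If the target set is
#' empty for the current disturbance estimate (zone unreachable under the
#' dose bounds) the cost is `Inf` with attribute `degenerate = TRUE`.
#'
#' @param xa,ua candidate artificial equilibrium.
#' @param zone a [zone_spec()].
#' @param aug the controller's [augmented_model][augment].
#' @param dhat current disturbance estimate.
#' @param P terminal weight.
#' @return scalar `P * (dist_x + dist_u)`.
#' @export
terminal_cost <- function(xa, ua, zone, aug, dhat = 0, P = 1e4) {
  nx <- nrow(aug$imp$Ad)
  proj <- function(wx, wu) {
    # min wx ||x - xa||^2 + wu (u - ua)^2 over the target equilibrium set
    D <- diag(c(rep(wx, nx), wu)) * 2
    D <- D + diag(1e-9, nx + 1L)
    dv <- 2 * c(rep(wx, nx) * xa, wu * ua)
    Ad <- aug$imp$Ad; BudD <- aug$imp$Bud
    w <- drop(aug$Bdd %*% dhat) + aug$imp$Ed
    Aeq <- cbind(diag(nx) - Ad, -BudD)     # nx x (nx+1)
    yrow <- c(drop(aug$imp$C), 0)
    yd <- drop(aug$dist$Cd %*% dhat)
    G <- rbind(yrow, -yrow,
               c(rep(0, nx), 1), c(rep(0, nx), -1))
    g <- c(zone$y_lo - yd, -(zone$y_hi - yd), zone$u_min, -zone$u_max)
    sol <- tryCatch(
      quadprog::solve.QP(D, dv, t(rbind(Aeq, G)), c(w, g), meq = nx),
      error = function(e) NULL)
    if (is.null(sol)) return(NULL)
    sol$solution
  }
  px <- proj(1, 1e-9)
  pu <- proj(1e-9, 1)
  if (is.null(px) || is.null(pu)) {
    res <- Inf
    attr(res, "degenerate") <- TRUE
    warning("target equilibrium set is empty for the current disturbance")
    return(res)
  }
  dist_x <- sqrt(sum((xa - px[1:nx])^2))
  dist_u <- abs(ua - pu[nx + 1L])
  P * (dist_x + dist_u)
}

#' One closed-loop control cycle
#'
#' Executes, in order: CGM reading -> estimator correction -> zone MPC
#' solve -> bolus applied to the plant -> plant advanced one period with
#' the true (unannounced) meal -> estimator prediction with the applied
#' bolus and r = 0 (the controller never sees meals).
#'
#' @param plant_x true plant state (length 5).
#' @param est the [augmented_estimate][estimator_init].
#' @param ctrl an [ofzmpc_controller()].
#' @param plant_imp the plant's `impulsive_model` (may differ from the
#'   controller's: plant-model mismatch).
#' @param meal_g grams of carbohydrate entering during this period.
#' @param y CGM sample (mg/dL); `NA` = dropout; `NULL` reads the plant's
#'   glycemia directly (noise-free sensor).
#' @param clamp clamp the plant glycemia at 1 mg/dL (the physical plant
#'   cannot go negative; the prediction model is never clamped).
#' @return list: `plant_x` (advanced), `est` (predicted to k+1), `sol`
#'   (the `control_solution`), `y`, and `projection` (the model's
#'   5-min-ahead CGM projection made this cycle).
#' @export
closed_loop_step <- function(plant_x, est, ctrl, plant_imp, meal_g = 0,
                             y = NULL, clamp = TRUE) {
  if (is.null(y)) y <- plant_x[1]
  est <- kalman_correct(est, y)
  se <- state_estimate(est)
  sol <- ofzmpc_step(ctrl, se$xhat, se$dhat)
  plant_x <- step(plant_imp, plant_x, sol$applied, meal_g)
  if (clamp && plant_x[1] < 1) plant_x[1] <- 1
  est <- kalman_predict(est, sol$applied, 0)
  projection <- drop(est$aug$Ctil %*% est$xhat)
  list(plant_x = plant_x, est = est, sol = sol, y = y,
       projection = projection)
}
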