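# Independent oracles used across the suite. These deliberately avoid the
# package's own matrix-exponential / QP code paths.

# Classical RK4 for the linear ODE xdot = A x + c (constant forcing).
rk4_integrate <- function(A, c_vec, x0, T, n = 2000L) {
  h <- T / n
  x <- x0
  f <- function(x) drop(A %*% x) + c_vec
  for (i in seq_len(n)) {
    k1 <- f(x)
    k2 <- f(x + h / 2 * k1)
    k3 <- f(x + h / 2 * k2)
    k4 <- f(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Noise-free bolus-response dataset from a known parameter set: a single
# bolus at t = 0 from an initial hyperglycemia, per the identification
# protocol (no meals in the window).
sim_bolus_dataset <- function(params, n = 80L, bolus = 1, y0 = 400, T = 5) {
  ds <- data.frame(time_min = (seq_len(n) - 1L) * T,
                   cgm = y0,
                   insulin_U = c(bolus, numeric(n - 1L)))
  ds$cgm <- simulate_response(params, ds)
  ds
}

# Hand-built one-compartment glycemia surrogate (decay a, insulin gain bu
# per unit dose-rate, production e) wrapped as a continuous_model so the
# controller machinery accepts it.
scalar_model <- function(a = 0.02, bu = -12, e = 2.2) {
  structure(list(A = matrix(-a, 1, 1), Bu = matrix(bu), Br = matrix(0),
                 E = e, C = matrix(1, 1, 1)),
            class = "continuous_model")
}

scalar_controller <- function(Hp, Hu, a = 0.02, bu = -12, e = 2.2,
                              R = 1, P = 1e4, T = 5) {
  imp <- discretize(scalar_model(a, bu, e), T)
  aug <- augment(imp, disturbance_model("custom", Bd = matrix(1, 1, 1),
                                        Cd = matrix(0, 1, 1)))
  ofzmpc_controller(aug, zone_spec(),
                    controller_config(Hp = Hp, Hu = Hu, T = T,
                                      Q = matrix(1), R = R, P = P))
}

# Exhaustive-search oracle for the scalar zone MPC: grid the first Hu - 1
# free doses and ua, solve the last free dose from the hard terminal
# equality, evaluate the exact cost (stage + R + quadratic zone slack).
# Returns the best feasible cost (Inf if none).
scalar_grid_oracle <- function(ctrl, x0, dhat = 0, n_grid = 25L) {
  cfg <- ctrl$cfg; zone <- ctrl$zone
  Ad <- drop(ctrl$Ad); Bud <- drop(ctrl$BudD)
  w <- drop(ctrl$Bdd %*% dhat) + drop(ctrl$Ed)
  Hp <- cfg$Hp; Hu <- cfg$Hu
  stopifnot(Hu == Hp)  # oracle written for the no-blocking tiny instances
  grid <- seq(zone$u_min, zone$u_max, length.out = n_grid)
  free <- Hu - 1L
  combos <- as.matrix(do.call(expand.grid,
                              c(rep(list(grid), free), list(ua = grid))))
  best <- Inf
  Q <- drop(cfg$Q)
  for (i in seq_len(nrow(combos))) {
    u_head <- combos[i, seq_len(free)]
    ua <- combos[i, free + 1L]
    xa <- (Bud * ua + w) / (1 - Ad)
    # propagate the first Hu-1 inputs, then solve the last one from
    # x(Hp) = xa
    x <- x0
    xs <- numeric(Hp)
    for (j in seq_len(free)) {
      xs[j] <- x
      x <- Ad * x + Bud * u_head[j] + w
    }
    xs[Hp] <- x
    u_last <- (xa - Ad * x - w) / Bud
    if (u_last < zone$u_min - 1e-9 || u_last > zone$u_max + 1e-9) next
    u <- c(u_head, u_last)
    ya <- xa
    s_lo <- max(0, zone$y_lo - ya)
    s_hi <- max(0, ya - zone$y_hi)
    cost <- sum(Q * (xs - xa)^2) + cfg$R * sum((u - ua)^2) +
      cfg$P * (s_lo^2 + s_hi^2)
    if (cost < best) best <- cost
  }
  best
}

# Simulate the controller's own prediction model (disturbance-corrected,
# r = 0) for cost cross-checks.
predict_trajectory <- function(ctrl, xhat, dhat, u_seq) {
  w <- drop(ctrl$Bdd %*% dhat) + ctrl$Ed
  n <- length(u_seq)
  out <- matrix(NA_real_, n + 1L, ctrl$nx)
  x <- as.numeric(xhat)
  out[1L, ] <- x
  for (k in seq_len(n)) {
    x <- drop(ctrl$Ad %*% x) + ctrl$BudD * u_seq[k] + w
    out[k + 1L, ] <- x
  }
  out
}

random_params <- function() {
  model_parameters(p0 = runif(1, 0.5, 15), p1 = runif(1, 0.002, 0.05),
                   p2 = runif(1, 200, 1500), p3 = runif(1, 5, 15),
                   p4 = runif(1, 2, 12), p5 = runif(1, 10, 40))
}
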