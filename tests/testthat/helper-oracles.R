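# Independent oracles used across the suite.

# Shooting solution of S'' = phi*S/(1+beta*S), S(0)=1, S'(1)=0, via a
# high-accuracy initial value integration (deSolve) and secant iteration on
# the unknown interface slope.  Independent of the package's finite
# difference solver.
shooting_oracle <- function(phi, beta, x_out = seq(0, 1, length.out = 101)) {
  rhs <- function(t, y, parms) {
    s <- max(y[1], 0)      # clamp so overshooting trial slopes stay regular
    list(c(y[2], phi * s / (1 + beta * s)))
  }
  shoot <- function(slope) {
    sol <- deSolve::ode(c(1, slope), c(0, 1), rhs, NULL,
                        method = "ode45", rtol = 1e-12, atol = 1e-12)
    sol[nrow(sol), 3]    # S'(1)
  }
  lo <- -phi
  hi <- 0
  f_lo <- shoot(lo)
  f_hi <- shoot(hi)
  stopifnot(f_lo * f_hi <= 0)
  slope <- stats::uniroot(shoot, c(lo, hi), tol = 1e-13)$root
  sol <- deSolve::ode(c(1, slope), x_out, rhs, NULL,
                      method = "ode45", rtol = 1e-12, atol = 1e-12)
  list(x = sol[, 1], s = sol[, 2], flux0 = slope)
}

# Quadrature of the reaction rate over a solved profile by adaptive
# integration of a spline interpolant (independent of the solver's own
# conservation identity).
rate_quadrature <- function(profile) {
  f <- stats::splinefun(profile$grid,
                        reaction_rate(profile$s_values, profile$phi_eff,
                                      profile$beta_eff, profile$regime),
                        method = "natural")
  stats::integrate(f, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
}

# Teacher-forced forward pass with the context matrix held fixed: the map
# whose exact Jacobian enn_jacobian() claims to compute.
forward_frozen_context <- function(theta, N, x, C) {
  w <- biofiltervoc:::enn_unpack(theta, N)
  y <- numeric(length(x))
  for (t in seq_along(x)) {
    h <- 1 / (1 + exp(-(as.vector(w$w_hi) * x[t] +
                          as.vector(w$w_hc %*% C[t, ]) + w$b_h)))
    y[t] <- 1 / (1 + exp(-(sum(as.vector(w$w_oh) * h) + w$b_o)))
  }
  y
}

# Central finite-difference Jacobian of the frozen-context map.
fd_jacobian_frozen <- function(theta, N, x, C, h = 1e-6) {
  J <- matrix(0, length(x), length(theta))
  for (j in seq_along(theta)) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (forward_frozen_context(up, N, x, C) -
                 forward_frozen_context(dn, N, x, C)) / (2 * h)
  }
  J
}
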