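test_that("solved profiles satisfy boundary conditions and shape invariants", {
  cases <- list(c(0.5, 0.5), c(10, 10), c(10, 300), c(4, 10), c(0.1, 10))
  for (pb in cases) {
    prof <- solve_biofilm_bvp(biofilm_params(phi = pb[1], beta = pb[2]))
    n <- length(prof$grid)
    expect_equal(prof$s_values[1], 1, tolerance = 1e-10)
    # Neumann condition at the support: quadratic one-sided slope
    h <- prof$grid[2] - prof$grid[1]
    slope1 <- (3 * prof$s_values[n] - 4 * prof$s_values[n - 1] +
                 prof$s_values[n - 2]) / (2 * h)
    expect_lt(abs(slope1), 1e-5)
    expect_true(all(prof$s_values >= 0 & prof$s_values <= 1))
    expect_true(all(diff(prof$s_values) <= 1e-14))
    expect_lte(prof$flux0, 0)
    expect_lt(prof$residual, 1e-12)
  }
})

test_that("no-reaction and pinene-modulus cases behave as expected", {
  p0 <- solve_biofilm_bvp(biofilm_params(phi = 0, beta = 5))
  expect_equal(p0$s_values, rep(1, length(p0$grid)))
  expect_equal(p0$flux0, 0)

  # pinene uses alpha * phi1: alpha=0.5, phi1=8 must equal methanol phi=4
  pm <- solve_biofilm_bvp(biofilm_params(phi = 4, beta = 10))
  pp <- solve_biofilm_bvp(biofilm_params(phi1 = 8, beta1 = 10, alpha = 0.5),
                          species = "pinene")
  expect_equal(pp$s_values, pm$s_values, tolerance = 1e-12)
  expect_equal(pp$phi_eff, 4)
})

test_that("finite-difference solution agrees with an independent shooting oracle", {
  skip_if_not_installed("deSolve")
  for (pb in list(c(10, 10), c(2, 0.5))) {
    or <- shooting_oracle(pb[1], pb[2])
    prof <- solve_biofilm_bvp(biofilm_params(phi = pb[1], beta = pb[2]),
                              n_grid = 101)
    expect_lt(max(abs(prof$s_values - or$s)), 1e-8)
    expect_lt(abs(prof$flux0 - or$flux0), 1e-8)
  }
})

test_that("first-order closed form satisfies its BVP and matches the solver", {
  x <- seq(0, 1, length.out = 41)
  expect_equal(analytic_first_order(0, x), rep(1, 41))
  expect_equal(analytic_first_order(1, 1), 1 / cosh(1))
  expect_equal(first_order_flux(1), -tanh(1))
  for (phi in c(0.1, 1, 10)) {
    s <- analytic_first_order(phi, x)
    expect_equal(s[1], 1)
    # closed-form derivative vanishes at x = 1
    eps <- 1e-7
    expect_lt(abs(analytic_first_order(phi, 1) -
                    analytic_first_order(phi, 1 - eps)) / eps, 1e-5)
    prof <- solve_biofilm_bvp(biofilm_params(phi = phi, beta = 0),
                              regime = "first_order", n_grid = 201)
    expect_lt(max(abs(prof$s_values - analytic_first_order(phi, prof$grid))),
              1e-10)
    expect_lt(abs(prof$flux0 - first_order_flux(phi)), 1e-8)
  }
  expect_error(analytic_first_order(-1, 0.5), ">= 0")
})

test_that("zero-order closed form handles both supply regimes", {
  x <- seq(0, 1, length.out = 101)
  expect_equal(analytic_zero_order(1, 1, 1), 0.5)    # d = 1: S(1) = 1 - d/2
  expect_equal(analytic_zero_order(0, 1, x), rep(1, 101))

  # depleted case d = 4: S(0) = 1 and S(x_p) = 0 with x_p = sqrt(1/2)
  x_p <- sqrt(0.5)
  expect_equal(analytic_zero_order(4, 1, 0), 1)
  expect_equal(analytic_zero_order(4, 1, x_p), 0)
  # C1 matching at the free boundary: value and slope continuous
  eps <- 1e-8
  expect_lt(analytic_zero_order(4, 1, x_p - eps), 1e-14)
  expect_equal((analytic_zero_order(4, 1, x_p - eps) -
                  analytic_zero_order(4, 1, x_p)) / eps, 0, tolerance = 1e-7)

  # discretized ODE residual of the parabola is exactly zero (to round-off)
  prof <- solve_biofilm_bvp(biofilm_params(phi = 3, beta = 2),
                            regime = "zero_order", n_grid = 101)
  h <- prof$grid[2] - prof$grid[1]
  s <- prof$s_values
  i <- 2:(length(s) - 1)
  resid <- (s[i - 1] - 2 * s[i] + s[i + 1]) / h^2 - 3 / 2
  expect_lt(max(abs(resid)), 1e-9)
  expect_error(analytic_zero_order(1, 0, x), "beta")
})

test_that("interface flux obeys conservation and the one-sided fallback works", {
  for (case in list(list(10, 10, "michaelis_menten"),
                    list(4, 10, "michaelis_menten"),
                    list(1, 0, "first_order"),
                    list(1, 2, "zero_order"))) {
    prof <- solve_biofilm_bvp(biofilm_params(phi = case[[1]], beta = case[[2]]),
                              regime = case[[3]])
    expect_lt(abs(abs(interface_flux(prof)) - rate_quadrature(prof)), 1e-6)
  }
  # raw profile without a stored slope: high-order one-sided difference
  x <- seq(0, 1, length.out = 201)
  raw <- list(grid = x, s_values = analytic_first_order(1, x))
  expect_equal(interface_flux(raw), -tanh(1), tolerance = 1e-8)
  expect_error(interface_flux(list(grid = x[1:3], s_values = x[1:3])), "5 points")
})

test_that("profiles respond monotonically to the kinetic parameters", {
  x_ref <- solve_biofilm_bvp(biofilm_params(phi = 10, beta = 10), n_grid = 101)
  # saturation grows with the initial-saturation parameter beta
  for (beta in c(15, 50, 300)) {
    p <- solve_biofilm_bvp(biofilm_params(phi = 10, beta = beta), n_grid = 101)
    expect_true(all(p$s_values >= x_ref$s_values - 1e-12))
    x_ref <- p
  }
  # and decays with the modulus phi
  p_ref <- solve_biofilm_bvp(biofilm_params(phi = 0.5, beta = 10), n_grid = 101)
  for (phi in c(1, 4, 10)) {
    p <- solve_biofilm_bvp(biofilm_params(phi = phi, beta = 10), n_grid = 101)
    expect_true(all(p$s_values <= p_ref$s_values + 1e-12))
    p_ref <- p
  }
})

test_that("Michaelis-Menten bridges its two limits as beta varies", {
  grid_err <- function(beta, phi = 10) {
    p <- solve_biofilm_bvp(biofilm_params(phi = phi, beta = beta), n_grid = 201)
    max(abs(p$s_values - analytic_zero_order(phi, beta, p$grid)))
  }
  # approach to the zero-order parabola is monotone in beta
  errs <- vapply(c(30, 100, 300, 1000), grid_err, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 5e-3)

  p <- solve_biofilm_bvp(biofilm_params(phi = 5, beta = 1e-8), n_grid = 201)
  expect_lt(max(abs(p$s_values - analytic_first_order(5, p$grid))), 1e-7)
})

test_that("grid refinement leaves the extrapolated solution unchanged", {
  p1 <- solve_biofilm_bvp(biofilm_params(phi = 10, beta = 10), n_grid = 501)
  p2 <- solve_biofilm_bvp(biofilm_params(phi = 10, beta = 10), n_grid = 1001)
  expect_lt(abs(p1$s_values[501] - p2$s_values[1001]), 1e-8)
  expect_error(solve_biofilm_bvp(biofilm_params(phi = 1, beta = 1), n_grid = 5),
               "n_grid")
})
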