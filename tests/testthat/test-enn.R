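tiny_weights <- function(N, w_hi = 0, w_hc = 0, b_h = 0, w_oh = 0, b_o = 0) {
  biofiltervoc:::new_enn_weights(
    matrix(w_hi, N, 1), matrix(w_hc, N, N), rep(b_h, N),
    matrix(w_oh, 1, N), b_o)
}

test_that("forward pass reproduces hand-evaluated cases", {
  sig <- function(z) 1 / (1 + exp(-z))

  # all-zero network: hidden sigmoid(0)=0.5, output sigmoid(0)=0.5
  fw <- enn_forward(tiny_weights(4), c(0.3, 0.9))
  expect_equal(fw$y, c(0.5, 0.5))
  expect_equal(fw$H[1, ], rep(0.5, 4))

  # single neuron, unit input/output weights, x = 0
  w <- tiny_weights(1, w_hi = 1, w_oh = 1)
  fw <- enn_forward(w, 0)
  expect_equal(fw$y, sig(0.5), tolerance = 1e-9)   # 0.622459

  # context propagation: with w_hc = 1, the step-2 hidden pre-activation
  # for x = 0 equals h(1)
  w <- tiny_weights(1, w_hc = 1, w_oh = 1)
  fw <- enn_forward(w, c(0.7, 0))
  expect_equal(fw$C[2, 1], fw$H[1, 1])
  expect_equal(fw$H[2, 1], sig(fw$H[1, 1]))
  expect_equal(fw$final_context, fw$H[2, ])

  expect_true(all(fw$y > 0 & fw$y < 1))
  expect_error(enn_forward(w, c(1, NA)), "finite")
})

test_that("dataset building splits 1001 points into 701/150/150 deterministically", {
  prof <- solve_biofilm_bvp(biofilm_params(phi = 1, beta = 1), n_grid = 101)
  ds <- build_dataset(prof, n = 1001, seed = 7)
  expect_equal(as.vector(table(ds$split_index)), c(701L, 150L, 150L))
  expect_equal(length(ds$x_points), 1001L)
  expect_false(any(is.na(ds$split_index)))         # exhaustive partition

  ds2 <- build_dataset(prof, n = 1001, seed = 7)
  expect_identical(ds$split_index, ds2$split_index)
  ds3 <- build_dataset(prof, n = 1001, seed = 8)
  expect_false(identical(ds$split_index, ds3$split_index))

  # interpolation from the solver grid is far below solver accuracy
  prof_fo <- solve_biofilm_bvp(biofilm_params(phi = 2, beta = 0),
                               regime = "first_order", n_grid = 1001)
  ds_fo <- build_dataset(prof_fo, n = 257, seed = 1)
  expect_lt(max(abs(ds_fo$targets - analytic_first_order(2, ds_fo$x_points))),
            1e-9)
  expect_error(build_dataset(prof, n = 5), "n")
  expect_error(build_dataset(prof, split = c(0.5, 0.5, 0.5)), "split")
})

test_that("largest-remainder rounding preserves totals", {
  expect_equal(biofiltervoc:::largest_remainder(1001, c(0.7, 0.15, 0.15)),
               c(701L, 150L, 150L))
  expect_equal(sum(biofiltervoc:::largest_remainder(100, c(1, 1, 1) / 3)), 100L)
})

test_that("the damped normal-equation solve has the textbook limits", {
  # scalar linear model y = w x, datum (1, 1), w = 0, mu = 1: delta = 0.5
  expect_equal(biofiltervoc:::lm_solve(matrix(1), 1, 1), 0.5)

  # mu -> 0 recovers the least-squares step; mu -> Inf kills the step
  set.seed(42)
  J <- matrix(rnorm(30), 10, 3)
  e <- rnorm(10)
  expect_equal(biofiltervoc:::lm_solve(J, e, 1e-12),
               qr.solve(J, e), tolerance = 1e-8)
  expect_lt(sqrt(sum(biofiltervoc:::lm_solve(J, e, 1e12)^2)), 1e-9)

  # primal (m >= p) and dual (m < p) paths agree
  Jw <- matrix(rnorm(30), 3, 10)
  ew <- rnorm(3)
  primal <- as.vector(solve(crossprod(Jw) + diag(0.1, 10), crossprod(Jw, ew)))
  expect_equal(biofiltervoc:::lm_solve(Jw, ew, 0.1), primal, tolerance = 1e-10)
})

test_that("lm_step proposes a finite candidate that reduces the linear model", {
  cfg <- enn_config(n_hidden = 3, seed = 5)
  w <- enn_init(cfg)
  x <- seq(0, 1, length.out = 20)
  targets <- analytic_first_order(1, x)
  st <- lm_step(w, x, targets, batch_idx = 1:20, mu = 1e-2)
  expect_s3_class(st$weights, "enn_weights")
  expect_true(all(is.finite(st$delta)))
  fw0 <- enn_forward(w, x)
  expect_lt(st$predicted_sse, sum((targets - fw0$y)^2))
  expect_error(lm_step(w, x, targets, 1:20, mu = 0), "mu")
})

test_that("teacher-forced analytic Jacobian matches finite differences", {
  cfg <- enn_config(n_hidden = 3, seed = 11)
  w <- enn_init(cfg)
  x <- seq(0, 1, length.out = 7)
  fw <- enn_forward(w, x)
  J <- biofiltervoc:::enn_jacobian(w, x, fw)
  theta <- biofiltervoc:::enn_pack(w)
  J_fd <- fd_jacobian_frozen(theta, 3, x, fw$C)
  denom <- pmax(abs(J_fd), 1e-8)
  expect_lt(max(abs(J - J_fd) / denom), 1e-5)
})

test_that("training is deterministic and its accepted-step MSE never rises", {
  prof <- solve_biofilm_bvp(biofilm_params(phi = 4, beta = 10), n_grid = 201)
  ds <- build_dataset(prof, n = 101, seed = 3)
  cfg <- enn_config(n_hidden = 6, max_iterations = 40, seed = 3)
  m1 <- enn_train(cfg, ds)
  m2 <- enn_train(cfg, ds)
  expect_identical(m1$record$mse_history, m2$record$mse_history)
  expect_identical(biofiltervoc:::enn_pack(m1$weights),
                   biofiltervoc:::enn_pack(m2$weights))
  expect_true(all(diff(m1$record$mse_history) <= 0))
  expect_lte(m1$record$epochs_run, 40)
  expect_true(m1$record$stop_reason %in%
                c("max_iter", "grad_tol", "mu_max", "val_patience"))
})

test_that("a constant target is learned to round-off via the output bias", {
  prof <- list(grid = seq(0, 1, length.out = 11), s_values = rep(0.5, 11))
  ds <- build_dataset(prof, n = 60, seed = 2)
  m <- enn_train(enn_config(n_hidden = 5, max_iterations = 50, seed = 2,
                            val_patience = Inf), ds)
  pred <- enn_predict(m$final_weights, ds$x_points)
  expect_lt(mean((pred - 0.5)^2), 1e-10)
})

test_that("prediction enforces the sequential contract", {
  cfg <- enn_config(n_hidden = 3, seed = 1)
  w <- enn_init(cfg)
  expect_identical(enn_predict(w, numeric(0)), numeric(0))
  expect_error(enn_predict(w, c(0.5, 0.2)), "ascending")
  expect_error(enn_predict(w, c(-0.1, 0.5)), "0, 1")
  x <- seq(0, 1, length.out = 9)
  expect_equal(enn_predict(w, x), enn_forward(w, x)$y)
})
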