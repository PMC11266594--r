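#' Elman network surrogate configuration
#'
#' Hyperparameters of the Elman recurrent network and its
#' Levenberg-Marquardt trainer.  Defaults follow the reference setup:
#' one hidden layer of 60 logistic neurons with a context copy, logistic
#' output, at most 2000 LM iterations, mean-square-error objective, and a
#' 70/15/15 train/validation/test split of a 1001-point dataset.
#'
#' @param n_hidden Hidden (and context) width.
#' @param n_in,n_out External input and output widths.
#' @param max_iterations LM epoch cap.
#' @param mu0 Initial damping.
#' @param mu_up,mu_down Damping multipliers on rejected / accepted steps.
#' @param mu_max Damping value at which training aborts as diverged.
#' @param grad_tol Stop when the MSE gradient infinity-norm falls below this.
#' @param val_patience Consecutive accepted steps with degrading validation
#'   MSE tolerated before stopping; `Inf` disables early stopping.
#'   Degrading means exceeding the best validation MSE by more than a
#'   relative 1e-6 -- a plateau at the optimum does not trigger a stop.
#' @param split Train/validation/test fractions, must sum to 1.
#' @param seed RNG seed for weight initialization (and dataset splitting
#'   when used through higher-level drivers).
#' @param hidden_activation,output_activation Only `"logistic"` is
#'   implemented; the arguments document the architecture.
#' @return Object of class `enn_config`.
#' @export
enn_config <- function(n_hidden = 60, n_in = 1, n_out = 1,
                       max_iterations = 2000, mu0 = 1e-3, mu_up = 10,
                       mu_down = 0.1, mu_max = 1e10, grad_tol = 1e-7,
                       val_patience = 6, split = c(0.70, 0.15, 0.15),
                       seed = 1L,
                       hidden_activation = "logistic",
                       output_activation = "logistic") {
  if (n_hidden < 1 || n_in < 1 || n_out < 1) stop("widths must be positive")
  if (max_iterations < 1) stop("`max_iterations` must be positive")
  if (mu0 <= 0 || mu_up <= 1 || mu_down <= 0 || mu_down >= 1 || mu_max <= mu0)
    stop("invalid damping schedule")
  if (length(split) != 3 || any(split < 0) || abs(sum(split) - 1) > 1e-12)
    stop("`split` must be three non-negative fractions summing to 1")
  hidden_activation <- match.arg(hidden_activation, "logistic")
  output_activation <- match.arg(output_activation, "logistic")
  if (n_in != 1 || n_out != 1)
    stop("only scalar input/output networks are implemented")
  structure(list(n_hidden = as.integer(n_hidden), n_in = 1L, n_out = 1L,
                 max_iterations = as.integer(max_iterations), mu0 = mu0,
                 mu_up = mu_up, mu_down = mu_down, mu_max = mu_max,
                 grad_tol = grad_tol, val_patience = val_patience,
                 split = split, seed = as.integer(seed),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "enn_config")
}

logistic <- function(z) 1 / (1 + exp(-z))

#' Initialize Elman network weights
#'
#' Draws all weights and biases uniformly from `[-0.5, 0.5]` using the
#' seed in `config`; the context (hidden-to-hidden) block is additionally
#' scaled by `1 / sqrt(n_hidden)` so that its summed contribution to the
#' hidden pre-activation has the same magnitude as a single input weight,
#' which keeps the teacher-forced Jacobian an accurate local model early
#' in training.
#'
#' @param config An [enn_config()].
#' @return Object of class `enn_weights`: `w_hi` (N x 1), `w_hc` (N x N),
#'   `b_h` (N), `w_oh` (1 x N), `b_o` (scalar).
#' @export
enn_init <- function(config) {
  stopifnot(inherits(config, "enn_config"))
  N <- config$n_hidden
  set.seed(config$seed)
  w_hi <- matrix(stats::runif(N, -0.5, 0.5), N, 1)
  w_hc <- matrix(stats::runif(N * N, -0.5, 0.5) / sqrt(N), N, N)
  b_h <- stats::runif(N, -0.5, 0.5)
  w_oh <- matrix(stats::runif(N, -0.5, 0.5), 1, N)
  b_o <- stats::runif(1, -0.5, 0.5)
  new_enn_weights(w_hi, w_hc, b_h, w_oh, b_o)
}

new_enn_weights <- function(w_hi, w_hc, b_h, w_oh, b_o) {
  w <- list(w_hi = w_hi, w_hc = w_hc, b_h = b_h, w_oh = w_oh, b_o = b_o)
  if (!all(vapply(w, function(m) all(is.finite(m)), logical(1))))
    stop("weights must be finite")
  structure(w, class = "enn_weights")
}

enn_pack <- function(w) {
  c(as.vector(w$w_hi), as.vector(w$w_hc), w$b_h, as.vector(w$w_oh), w$b_o)
}

enn_unpack <- function(theta, N) {
  i <- 0L
  w_hi <- matrix(theta[(i + 1L):(i + N)], N, 1); i <- i + N
  w_hc <- matrix(theta[(i + 1L):(i + N * N)], N, N); i <- i + N * N
  b_h <- theta[(i + 1L):(i + N)]; i <- i + N
  w_oh <- matrix(theta[(i + 1L):(i + N)], 1, N); i <- i + N
  new_enn_weights(w_hi, w_hc, b_h, w_oh, theta[i + 1L])
}

#' Forward pass of the Elman network
#'
#' Processes an ordered input sequence.  At step `t` the hidden layer sees
#' the external input and the context (previous hidden state):
#' `h(t) = sigma(w_hi x(t) + w_hc c(t-1) + b_h)`, `c(t) = h(t)`, and the
#' output is `y(t) = sigma(w_oh h(t) + b_o)`, with `sigma` the logistic
#' function, so outputs lie in `(0, 1)`.
#'
#' @param weights An `enn_weights` object.
#' @param x_sequence Ordered numeric external inputs.
#' @param c0 Initial context (defaults to the zero vector).
#' @return List with `y` (outputs), `H` (hidden states, T x N), `C`
#'   (contexts consumed at each step, T x N) and `final_context`.
#' @export
enn_forward <- function(weights, x_sequence, c0 = NULL) {
  stopifnot(inherits(weights, "enn_weights"))
  if (!all(is.finite(x_sequence))) stop("inputs must be finite")
  N <- nrow(weights$w_hi)
  if (is.null(c0)) c0 <- numeric(N)
  if (length(c0) != N) stop("`c0` must have length n_hidden")
  Tn <- length(x_sequence)
  H <- matrix(0, Tn, N)
  C <- matrix(0, Tn, N)
  y <- numeric(Tn)
  c_prev <- c0
  w_hi <- as.vector(weights$w_hi)
  w_oh <- as.vector(weights$w_oh)
  for (t in seq_len(Tn)) {
    h <- logistic(w_hi * x_sequence[t] +
                    as.vector(weights$w_hc %*% c_prev) + weights$b_h)
    H[t, ] <- h
    C[t, ] <- c_prev
    y[t] <- logistic(sum(w_oh * h) + weights$b_o)
    c_prev <- h
  }
  list(y = y, H = H, C = C, final_context = c_prev)
}

# Teacher-forced Jacobian of the outputs with respect to all weights and
# biases: the context rows C of a forward pass are treated as exogenous
# inputs, so no derivative flows through the recurrence.  Column order
# matches enn_pack().
enn_jacobian <- function(weights, x_sequence, fw) {
  N <- nrow(weights$w_hi)
  Tn <- length(x_sequence)
  yp <- fw$y * (1 - fw$y)                       # sigma'(output pre-act)
  Hp <- fw$H * (1 - fw$H)                       # sigma'(hidden pre-act)
  D <- yp * sweep(Hp, 2, as.vector(weights$w_oh), `*`)   # T x N
  J_whc <- matrix(0, Tn, N * N)
  for (k in seq_len(N))
    J_whc[, ((k - 1L) * N + 1L):(k * N)] <- D * fw$C[, k]
  cbind(D * x_sequence, J_whc, D, yp * fw$H, matrix(yp, Tn, 1))
}

#' One Levenberg-Marquardt step
#'
#' Solves `(J'J + mu I) dw = J' e` for the damped Gauss-Newton update,
#' where `e` are the residuals `target - output` on the batch and `J` the
#' teacher-forced Jacobian.  When the batch has fewer points than the
#' network has parameters the equivalent dual system
#' `dw = J'(JJ' + mu I)^{-1} e` is solved instead (same update, smaller
#' factorization).
#'
#' @param weights Current `enn_weights`.
#' @param x_sequence Full ordered input sequence.
#' @param targets Targets for every sequence point.
#' @param batch_idx Indices of the sequence points forming the batch.
#' @param mu Damping parameter, `> 0`.
#' @return List with `weights` (candidate), `delta` (packed update) and
#'   `predicted_sse` (batch sum of squares predicted by the linear model).
#' @export
lm_step <- function(weights, x_sequence, targets, batch_idx, mu) {
  if (mu <= 0) stop("`mu` must be > 0")
  fw <- enn_forward(weights, x_sequence)
  J <- enn_jacobian(weights, x_sequence, fw)[batch_idx, , drop = FALSE]
  e <- (targets - fw$y)[batch_idx]
  if (!all(is.finite(J))) stop("non-finite Jacobian")
  delta <- lm_solve(J, e, mu)
  pred <- e - as.vector(J %*% delta)
  list(weights = enn_unpack(enn_pack(weights) + delta, nrow(weights$w_hi)),
       delta = delta, predicted_sse = sum(pred^2))
}

lm_solve <- function(J, e, mu) {
  m <- nrow(J)
  p <- ncol(J)
  if (m < p) {
    as.vector(crossprod(J, solve(tcrossprod(J) + diag(mu, m), e)))
  } else {
    as.vector(solve(crossprod(J) + diag(mu, p), crossprod(J, e)))
  }
}

#' Build a surrogate training dataset from a biofilm profile
#'
#' Samples the reference profile at `n` uniformly spaced depths in
#' `[0, 1]` (re-using solver values exactly when the grids coincide,
#' natural cubic spline interpolation otherwise) and assigns each point to
#' the train/validation/test split by a seeded random permutation with
#' largest-remainder rounding of the split sizes.
#'
#' @param profile A `biofilm_profile` (or list with `grid`, `s_values`).
#' @param n Number of points (default 1001), `>= 10`.
#' @param split Train/validation/test fractions summing to 1.
#' @param seed RNG seed for the permutation.
#' @return Object of class `enn_dataset`: `x_points`, `targets`,
#'   `split_index` (factor with levels train/val/test), `seed`.
#' @examples
#' prof <- solve_biofilm_bvp(biofilm_params(phi = 10, beta = 10))
#' ds <- build_dataset(prof, seed = 1)
#' table(ds$split_index)     # 701 / 150 / 150
#' @export
build_dataset <- function(profile, n = 1001, split = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  if (n < 10) stop("`n` must be >= 10")
  if (length(split) != 3 || any(split < 0) || abs(sum(split) - 1) > 1e-12)
    stop("`split` must be three non-negative fractions summing to 1")
  x <- seq(0, 1, length.out = n)
  if (length(profile$grid) == n && max(abs(profile$grid - x)) < 1e-12) {
    targets <- profile$s_values
  } else {
    targets <- stats::spline(profile$grid, profile$s_values, xout = x,
                             method = "natural")$y
  }
  sizes <- largest_remainder(n, split)
  set.seed(seed)
  perm <- sample.int(n)
  lab <- rep(c("train", "val", "test"), times = sizes)
  split_index <- factor(character(n), levels = c("train", "val", "test"))
  split_index[perm] <- lab
  structure(list(x_points = x, targets = targets, split_index = split_index,
                 seed = as.integer(seed)),
            class = "enn_dataset")
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1
  }
  as.integer(sizes)
}

#' Train the Elman surrogate by Levenberg-Marquardt
#'
#' Iterates [lm_step()] on the training split of the full ascending
#' sequence (the recurrent forward pass always runs over all points; only
#' the residuals at training indices enter the update).  A candidate is
#' accepted when it lowers the training MSE, upon which `mu` shrinks by
#' `mu_down`; otherwise `mu` grows by `mu_up` and the step is recomputed.
#' Because the teacher-forced Jacobian is an approximation, a rejected
#' full step is also retried at half and quarter length before the damping
#' is increased.  Training stops at `max_iterations`, when the MSE
#' gradient infinity-norm falls below `grad_tol`, when `mu` exceeds
#' `mu_max`, or when the validation MSE degrades for `val_patience`
#' consecutive accepted steps; the weights with the best validation MSE
#' are returned.
#'
#' @param config An [enn_config()].
#' @param dataset An [build_dataset()] result.
#' @return Object of class `enn_model`: `weights` (best-validation),
#'   `final_weights`, `config`, `dataset`, and `record` with
#'   `mse_history` (accepted-step train MSE), `val_history`,
#'   `best_val_mse`, `epochs_run`, `stop_reason`.
#' @export
enn_train <- function(config, dataset) {
  stopifnot(inherits(config, "enn_config"), inherits(dataset, "enn_dataset"))
  N <- config$n_hidden
  x <- dataset$x_points
  S <- dataset$targets
  tr <- which(dataset$split_index == "train")
  va <- which(dataset$split_index == "val")
  if (length(tr) < N + 2L)
    warning("fewer training points than hidden units + 2; fit may be rank-deficient")

  weights <- enn_init(config)
  theta <- enn_pack(weights)
  mu <- config$mu0
  best_val <- Inf
  best_theta <- theta
  patience_count <- 0
  mse_history <- numeric(0)
  val_history <- numeric(0)
  stop_reason <- "max_iter"
  epochs <- 0L

  for (epoch in seq_len(config$max_iterations)) {
    epochs <- epoch
    w <- enn_unpack(theta, N)
    fw <- enn_forward(w, x)
    e <- S - fw$y
    train_mse <- mean(e[tr]^2)
    J <- enn_jacobian(w, x, fw)[tr, , drop = FALSE]
    et <- e[tr]
    grad <- 2 * as.vector(crossprod(J, et)) / length(tr)
    if (max(abs(grad)) < config$grad_tol) {
      stop_reason <- "grad_tol"
      break
    }
    G <- tcrossprod(J)

    accepted <- FALSE
    while (!accepted && mu <= config$mu_max) {
      delta <- as.vector(crossprod(J, solve(G + diag(mu, length(tr)), et)))
      for (frac in c(1, 0.5, 0.25)) {
        cand <- theta + frac * delta
        fw_c <- enn_forward(enn_unpack(cand, N), x)
        cand_mse <- mean((S - fw_c$y)[tr]^2)
        if (cand_mse < train_mse) {
          theta <- cand
          mu <- mu * config$mu_down
          accepted <- TRUE
          mse_history <- c(mse_history, cand_mse)
          val_mse <- if (length(va)) mean((S - fw_c$y)[va]^2) else NA_real_
          val_history <- c(val_history, val_mse)
          if (length(va)) {
            if (val_mse < best_val) {
              if (val_mse < best_val * (1 - 1e-6) || !is.finite(best_val))
                patience_count <- 0
              best_val <- val_mse
              best_theta <- theta
            } else if (val_mse > best_val * (1 + 1e-6)) {
              patience_count <- patience_count + 1
            }
          }
          break
        }
      }
      if (!accepted) mu <- mu * config$mu_up
    }
    if (!accepted) {
      stop_reason <- "mu_max"
      break
    }
    if (length(va) && patience_count >= config$val_patience) {
      stop_reason <- "val_patience"
      break
    }
  }

  final_theta <- theta
  if (!length(va) || !is.finite(best_val)) best_theta <- final_theta
  structure(list(weights = enn_unpack(best_theta, N),
                 final_weights = enn_unpack(final_theta, N),
                 config = config, dataset = dataset,
                 record = list(mse_history = mse_history,
                               val_history = val_history,
                               best_val_mse = best_val,
                               epochs_run = epochs,
                               stop_reason = stop_reason)),
            class = "enn_model")
}

#' @export
print.enn_model <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<enn_model> %d hidden units, %d epochs, stop: %s\n  final train MSE %.3e, best val MSE %.3e\n",
    x$config$n_hidden, r$epochs_run, r$stop_reason,
    if (length(r$mse_history)) r$mse_history[length(r$mse_history)] else NA,
    r$best_val_mse))
  invisible(x)
}

#' Evaluate the surrogate at ascending depths
#'
#' Runs the recurrent forward pass from zero initial context over
#' `x_points`, which must be ascending: the context makes the output
#' order-dependent, so an unsorted query is rejected rather than silently
#' reordered.
#'
#' @param object An `enn_model` (uses the best-validation weights) or an
#'   `enn_weights` object.
#' @param x_points Ascending depths in `[0, 1]`.
#' @return Surrogate saturation values.
#' @export
enn_predict <- function(object, x_points) {
  weights <- if (inherits(object, "enn_model")) object$weights else object
  stopifnot(inherits(weights, "enn_weights"))
  if (length(x_points) == 0) return(numeric(0))
  if (any(x_points < 0 | x_points > 1)) stop("`x_points` must lie in [0, 1]")
  if (is.unsorted(x_points, strictly = FALSE))
    stop("`x_points` must be ascending (the context layer makes the output order-dependent)")
  enn_forward(weights, x_points)$y
}

#' @export
predict.enn_model <- function(object, x_points, ...) {
  enn_predict(object, x_points)
}
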