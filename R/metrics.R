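#' Mean absolute deviation between prediction and reference
#'
#' `MAD = mean(|pred - truth|)` over paired points.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Scalar `>= 0`.
#' @examples
#' mad_dev(c(1, 2, 4), c(1, 2, 3))   # 1/3
#' @export
mad_dev <- function(pred, truth) {
  check_pair(pred, truth)
  mean(abs(pred - truth))
}

#' Mean squared error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Scalar `>= 0`.
#' @export
mse <- function(pred, truth) {
  check_pair(pred, truth)
  mean((pred - truth)^2)
}

#' Theil inequality coefficient
#'
#' `TIC = rms(pred - truth) / (rms(pred) + rms(truth))`, a scale-invariant
#' disagreement measure in `[0, 1]` (0 for identical vectors, 1 for
#' maximal disagreement such as `pred = -truth`).
#'
#' @param pred,truth Equal-length numeric vectors, not both all-zero.
#' @return Scalar in `[0, 1]`.
#' @examples
#' tic(c(0, 0), c(1, 1))   # 1
#' @export
tic <- function(pred, truth) {
  check_pair(pred, truth)
  rms <- function(v) sqrt(mean(v^2))
  denom <- rms(pred) + rms(truth)
  if (denom == 0) stop("TIC undefined: both vectors are all-zero")
  rms(pred - truth) / denom
}

#' Nash-Sutcliffe efficiency and its complement
#'
#' `NSE = 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)`
#' (1 for a perfect prediction, 0 for the mean-of-reference predictor) and
#' `ENSE = 1 - NSE`.
#'
#' The printed form of the statistic in the source literature pairs a
#' `1/M`-scaled numerator with the deviations of the *prediction* from
#' the reference mean in the denominator; that variant is available as
#' `variant = "printed_form"` but is not the default because it is
#' undefined for the mean predictor itself.
#'
#' @param pred,truth Equal-length numeric vectors; `truth` must not be
#'   constant.
#' @param variant `"classical"` (default) or `"printed_form"`.
#' @return Named list with elements `nse` and `ense`.
#' @examples
#' nse_ense(c(0, 1, 1), c(0, 1, 2))$nse   # 0.5
#' @export
nse_ense <- function(pred, truth, variant = c("classical", "printed_form")) {
  check_pair(pred, truth)
  variant <- match.arg(variant)
  if (variant == "classical") {
    denom <- sum((truth - mean(truth))^2)
    if (denom == 0) stop("NSE undefined: reference vector is constant")
    nse <- 1 - sum((pred - truth)^2) / denom
  } else {
    denom <- sum((pred - mean(truth))^2)
    if (denom == 0) stop("printed-form NSE undefined: prediction coincides with the reference mean")
    nse <- 1 - mean((pred - truth)^2) / denom
  }
  list(nse = nse, ense = 1 - nse)
}

check_pair <- function(pred, truth) {
  if (!is.numeric(pred) || !is.numeric(truth)) stop("inputs must be numeric")
  if (length(pred) != length(truth)) stop("`pred` and `truth` lengths differ")
  if (length(pred) == 0) stop("inputs must be non-empty")
  invisible(TRUE)
}

#' Full metric report for one prediction/reference pair
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return Object of class `metric_report`: list with `mse`, `mad`, `tic`,
#'   `nse`, `ense`.
#' @export
metric_report <- function(pred, truth) {
  ne <- nse_ense(pred, truth)
  structure(list(mse = mse(pred, truth), mad = mad_dev(pred, truth),
                 tic = tic(pred, truth), nse = ne$nse, ense = ne$ense),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MSE %.3e  MAD %.3e  TIC %.3e  NSE %.6f  ENSE %.3e\n",
              x$mse, x$mad, x$tic, x$nse, x$ense))
  invisible(x)
}

#' Aggregate metrics over repeated stochastic trainings
#'
#' Minimum, mean and sample standard deviation (`ddof = 1`) of each metric
#' across independent training runs of the surrogate.
#'
#' @param reports List of at least two [metric_report()] objects.
#' @param scenario Label for the parameter scenario.
#' @return Object of class `run_statistics`: a data frame with columns
#'   `scenario`, `metric`, `min`, `mean`, `sd`, plus attribute `n_runs`.
#' @export
aggregate_runs <- function(reports, scenario = "") {
  if (length(reports) < 2) stop("at least two runs are required")
  if (!all(vapply(reports, inherits, logical(1), "metric_report")))
    stop("`reports` must be a list of metric_report objects")
  metrics <- c("mse", "mad", "tic", "nse", "ense")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, `[[`, numeric(1), m)
    data.frame(scenario = scenario, metric = m, min = min(v),
               mean = mean(v), sd = stats::sd(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_runs") <- length(reports)
  class(out) <- c("run_statistics", "data.frame")
  out
}
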