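#' Compare a model-projected prevalence with empiric cohort data
#'
#' Computes the empiric proportion \code{count/n}, an exact
#' (Clopper–Pearson) binomial confidence interval at the given level, and
#' whether the model estimate lies inside that interval — the model-vs-
#' cohort consistency check used when the projection horizon matches the
#' observed follow-up.
#'
#' The interval uses the standard beta-quantile closed form: lower bound
#' \code{qbeta(a/2, k, n-k+1)} (0 when k = 0) and upper bound
#' \code{qbeta(1-a/2, k+1, n-k)} (1 when k = n).
#'
#' @param model_estimate Projected prevalence (probability in [0, 1]).
#' @param empiric_count Number of empiric cases (0..n).
#' @param empiric_n Empiric denominator (> 0).
#' @param level Confidence level (default 0.95).
#' @return A list of class \code{validation_comparison}: model estimate,
#'   empiric count/n/proportion, interval bounds, and \code{consistent}.
#' @examples
#' validate_against_empiric(0.0352, empiric_count = 9, empiric_n = 290)
#' @export
validate_against_empiric <- function(model_estimate, empiric_count,
                                     empiric_n, level = 0.95) {
  if (empiric_n <= 0 || empiric_n != round(empiric_n)) {
    stop("empiric_n must be a positive integer", call. = FALSE)
  }
  if (empiric_count < 0 || empiric_count > empiric_n ||
      empiric_count != round(empiric_count)) {
    stop("empiric_count must be an integer in 0..empiric_n", call. = FALSE)
  }
  if (model_estimate < 0 || model_estimate > 1) {
    stop("model_estimate must be a probability", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  k <- empiric_count
  n <- empiric_n
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  structure(list(
    model_estimate = model_estimate,
    empiric_count = k,
    empiric_n = n,
    empiric_proportion = k / n,
    empiric_interval = c(lower = lower, upper = upper),
    level = level,
    consistent = model_estimate >= lower && model_estimate <= upper
  ), class = "validation_comparison")
}

#' @export
print.validation_comparison <- function(x, ...) {
  cat(sprintf(
    "Model %.2f%% vs empiric %d/%d = %.2f%% (%.0f%% CI %.2f-%.2f%%): %s\n",
    100 * x$model_estimate, x$empiric_count, x$empiric_n,
    100 * x$empiric_proportion, 100 * x$level,
    100 * x$empiric_interval["lower"], 100 * x$empiric_interval["upper"],
    if (x$consistent) "consistent" else "NOT consistent"))
  invisible(x)
}
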