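#' Smoothness ratio of a series
#'
#' `rho(k) = x(k) / sum_{i < k} x(i)` for k = 3..n: the k-th value relative
#' to the mass already accumulated. Small, decaying ratios indicate a
#' series whose accumulation will look exponential — the admissibility
#' heuristic for grey modeling.
#'
#' @param x Numeric vector or [grey_series()] with at least 3 points and
#'   positive partial sums.
#'
#' @return Numeric vector named by k = 3..n.
#' @examples
#' round(smoothness_ratio(beef_fixture()$train)[["3"]], 3)   # 0.718
#' @export
smoothness_ratio <- function(x) {
  gs <- as_grey_series(x, min_length = 3L)
  partial <- cumsum(gs$values)
  k <- 3:gs$n
  if (any(partial[k - 1L] <= 0)) {
    stop("zero partial sum: smoothness ratio undefined", call. = FALSE)
  }
  stats::setNames(gs$values[k] / partial[k - 1L], k)
}

#' Quasi-smoothness modeling-condition check
#'
#' A series is quasi-smooth when every smoothness ratio `rho(k)` (k = 3..n)
#' stays within `[0, epsilon]` and every consecutive ratio
#' `lambda(k) = rho(k) / rho(k-1)` (k = 4..n) stays below 1, i.e. the
#' relative contribution of new values is small and shrinking. Failing the
#' check does not block model fitting — it flags that the exponential-trend
#' assumption behind grey models is doubtful for this series.
#'
#' @param x Numeric vector or [grey_series()].
#' @param epsilon Upper bound on the smoothness ratios; the conventional
#'   threshold is 0.8.
#'
#' @return A list of class `smoothness_report`: `rho` (named, k = 3..n),
#'   `lambda` (named by the numerator index, k = 4..n), `epsilon`,
#'   `rho_ok`, `lambda_ok`, `quasi_smooth`.
#' @examples
#' quasi_smooth_check(beef_fixture()$train)$quasi_smooth   # TRUE
#' quasi_smooth_check(c(1, 2, 4, 8, 16))$quasi_smooth      # FALSE
#' @export
quasi_smooth_check <- function(x, epsilon = 0.8) {
  rho <- smoothness_ratio(x)
  lambda <- if (length(rho) >= 2L) {
    stats::setNames(rho[-1L] / rho[-length(rho)],
                    names(rho)[-1L])
  } else {
    stats::setNames(numeric(0), character(0))
  }
  rho_ok <- all(rho <= epsilon)
  lambda_ok <- all(lambda < 1)
  structure(list(rho = rho, lambda = lambda, epsilon = epsilon,
                 rho_ok = rho_ok, lambda_ok = lambda_ok,
                 quasi_smooth = rho_ok && lambda_ok),
            class = "smoothness_report")
}

#' @export
print.smoothness_report <- function(x, digits = 3, ...) {
  cat("Quasi-smoothness check (epsilon = ", x$epsilon, ")\n", sep = "")
  cat("  rho(k), k = ", names(x$rho)[1], "..",
      names(x$rho)[length(x$rho)], ": max ",
      round(max(x$rho), digits),
      if (x$rho_ok) " <= " else " > ", x$epsilon, "\n", sep = "")
  if (length(x$lambda)) {
    cat("  lambda(k): max ", round(max(x$lambda), digits),
        if (x$lambda_ok) " < 1" else " >= 1", "\n", sep = "")
  }
  cat(if (x$quasi_smooth) "  PASS: series is quasi-smooth\n"
      else "  FAIL: series is not quasi-smooth\n")
  invisible(x)
}

#' Simulation error report
#'
#' Residuals, per-point relative simulation percentage errors (RSPE,
#' stored as fractions) and their mean (MRSPE) for a fitted-vs-actual
#' pair. When a satisfaction threshold `alpha` is supplied, the report
#' also records whether `mrspe < alpha`.
#'
#' @param actual Observed values (all > 0).
#' @param fitted Simulated values, same length.
#' @param alpha Optional satisfaction threshold, as a fraction.
#'
#' @return A list of class `error_report`: `residuals`, `rspe`, `mrspe`
#'   (fractions), `alpha`, `satisfactory` (NA when `alpha` is NULL).
#' @examples
#' er <- error_report(c(100, 200), c(110, 190))
#' 100 * er$mrspe   # 7.5
#' @export
error_report <- function(actual, fitted, alpha = NULL) {
  actual <- as.numeric(actual)
  fitted <- as.numeric(fitted)
  if (length(actual) != length(fitted)) {
    stop("actual and fitted differ in length", call. = FALSE)
  }
  if (any(actual <= 0)) {
    stop("relative errors need strictly positive actual values",
         call. = FALSE)
  }
  residuals <- actual - fitted
  rspe <- abs(residuals / actual)
  mrspe <- mean(rspe)
  structure(list(residuals = residuals, rspe = rspe, mrspe = mrspe,
                 alpha = alpha,
                 satisfactory = if (is.null(alpha)) NA else mrspe < alpha),
            class = "error_report")
}

#' @export
print.error_report <- function(x, digits = 2, ...) {
  cat("Error report: MRSPE = ",
      format(round(100 * x$mrspe, digits), nsmall = digits), "% over ",
      length(x$rspe), " points\n", sep = "")
  if (!is.null(x$alpha)) {
    cat("  threshold ", 100 * x$alpha, "%: ",
        if (isTRUE(x$satisfactory)) "satisfactory" else "not satisfactory",
        "\n", sep = "")
  }
  invisible(x)
}

#' Mean relative prediction error on a holdout
#'
#' `mean(|predicted - actual| / actual)` over withheld periods, returned
#' as a fraction (multiply by 100 for percent).
#'
#' @param predicted Forecasts.
#' @param actual Withheld actuals, same length, all > 0.
#'
#' @return A nonnegative scalar fraction.
#' @examples
#' p <- c(740.59, 751.21, 783.11)
#' round(100 * holdout_mrpe(p, c(767, 794, 814)), 2)   # 4.21
#' @export
holdout_mrpe <- function(predicted, actual) {
  predicted <- as.numeric(predicted)
  actual <- as.numeric(actual)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length", call. = FALSE)
  }
  if (length(actual) == 0L) {
    stop("empty holdout", call. = FALSE)
  }
  if (any(actual <= 0)) {
    stop("relative errors need strictly positive actual values",
         call. = FALSE)
  }
  mean(abs(predicted - actual) / actual)
}
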