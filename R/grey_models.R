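#' Build the least-squares design system of EGM(1,1,r)
#'
#' Assembles the response vector and design matrix of the grey difference
#' equation `x^(r-1)(k) + a z^(r)(k) = b`: the response is
#' `Y(k) = x^(r)(k) - x^(r)(k-1)` (the (r-1)-order accumulation increment)
#' and the design rows are `(-z^(r)(k), 1)`, for k = 2..n. At `r = 1` the
#' response reduces to the original values and the system is the classic
#' even GM(1,1) one.
#'
#' @param x Numeric vector or [grey_series()] of at least 4 points.
#' @param r Accumulation order, positive real.
#'
#' @return A list of class `grey_design` with elements `Y` (length n-1),
#'   `B` ((n-1) x 2 matrix, second column all ones) and `r`.
#' @export
build_design <- function(x, r) {
  gs <- as_grey_series(x, min_length = 4L)
  check_order(r)
  xr <- fractional_accumulate(gs$values, r)
  Y <- diff(xr)
  B <- cbind(-mean_sequence(xr), 1)
  colnames(B) <- c("neg_z", "intercept")
  structure(list(Y = Y, B = B, r = r), class = "grey_design")
}

#' Least-squares estimate of the grey parameters
#'
#' Solves the overdetermined system `B [a, b]' = Y` in the least-squares
#' sense, i.e. the normal-equations solution `(B'B)^{-1} B'Y`, computed by
#' QR factorization for numerical stability.
#'
#' @param design A `grey_design` from [build_design()], or any list with
#'   elements `Y` and `B`.
#'
#' @return Named numeric vector `c(a = ..., b = ...)`: the development
#'   coefficient and grey input.
#' @export
grey_least_squares <- function(design) {
  B <- design$B
  Y <- design$Y
  if (nrow(B) < 2L) {
    stop("least squares needs at least 2 rows", call. = FALSE)
  }
  qrB <- qr(B)
  if (qrB$rank < 2L) {
    stop("design matrix is rank-deficient (background values carry no ",
         "information); cannot estimate (a, b)", call. = FALSE)
  }
  coefs <- qr.coef(qrB, Y)
  stats::setNames(as.numeric(coefs), c("a", "b"))
}

#' Recurrence coefficients of the time response
#'
#' Maps the grey parameters (a, b) to the coefficients of the accumulated
#' time-response recurrence `x^(r)(k) = delta1 x^(r)(k-1) + delta2`:
#' `delta1 = (1 - 0.5 a) / (1 + 0.5 a)`, `delta2 = b / (1 + 0.5 a)`.
#'
#' @param a Development coefficient.
#' @param b Grey input.
#'
#' @return Named numeric vector `c(delta1 = ..., delta2 = ...)`.
#' @examples
#' derived_params(0, 5)    # delta1 = 1, delta2 = 5
#' @export
derived_params <- function(a, b) {
  if (!is.finite(a) || !is.finite(b)) {
    stop("a and b must be finite", call. = FALSE)
  }
  denom <- 1 + 0.5 * a
  if (denom == 0) {
    stop("a = -2 makes the recurrence coefficients undefined",
         call. = FALSE)
  }
  c(delta1 = (1 - 0.5 * a) / denom, delta2 = b / denom)
}

#' Accumulated time response of EGM(1,1,r)
#'
#' Iterates `x^(r)(k) = delta1 x^(r)(k-1) + delta2` from the anchored first
#' accumulated value, for k = 1..horizon. Equivalent to the closed form
#' `delta1^(k-1) x^(r)(1) + sum_{i=0..k-2} delta1^i delta2`.
#'
#' @param delta1,delta2 Recurrence coefficients from [derived_params()].
#' @param first_value The anchored accumulated first value `x^(r)(1)`
#'   (equal to the first original value).
#' @param horizon Number of values to produce (>= 1).
#'
#' @return Numeric vector of length `horizon`; element 1 is `first_value`.
#' @export
time_response <- function(delta1, delta2, first_value, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      horizon != floor(horizon)) {
    stop("horizon must be a positive integer", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  out <- numeric(horizon)
  out[1L] <- first_value
  if (horizon > 1L) {
    for (k in 2:horizon) out[k] <- delta1 * out[k - 1L] + delta2
  }
  out
}

# Shared assembly of a fitted-model object. fitted/residuals/rspe cover
# k = 2..n only: there is no simulated value for the anchored first point.
new_grey_fit <- function(model, gs, r, coef, extra, fitted_full) {
  actual <- gs$values[-1L]
  fitted <- fitted_full[-1L]
  residuals <- actual - fitted
  if (any(actual == 0)) {
    rspe <- rep(NA_real_, length(actual))
    mrspe <- NA_real_
  } else {
    rspe <- abs(residuals / actual)
    mrspe <- mean(rspe)
  }
  structure(
    c(list(model = model, series = gs, r = r, coef = coef,
           fitted = fitted, residuals = residuals,
           rspe = rspe, mrspe = mrspe),
      extra),
    class = "grey_fit")
}

#' Fit the fractional-order even grey model EGM(1,1,r)
#'
#' The full pipeline: r-order accumulation of the original series,
#' least-squares estimation of the grey difference equation
#' `x^(r-1)(k) + a z^(r)(k) = b`, the delta-recurrence time response
#' anchored at `x^(r)(1) = x^(0)(1)`, and inversion by the fractional
#' difference. Simulated values are produced for k = 2..n; relative
#' simulation errors (RSPE) and their mean (MRSPE) are attached.
#'
#' @param x Numeric vector or [grey_series()] of at least 4 nonnegative
#'   points.
#' @param r Accumulation order. Use [optimize_order_pso()] or
#'   [grid_search_order()] to choose it from the data.
#'
#' @return An object of class `grey_fit` with elements `model`, `series`,
#'   `r`, `coef` (a, b), `delta` (delta1, delta2), `fitted`, `residuals`,
#'   `rspe`, `mrspe` (both as fractions, not percent).
#' @examples
#' beef <- beef_fixture()
#' fit <- fit_egm11r(beef$train, r = 0.436213)
#' round(100 * fit$mrspe, 2)   # 5.35
#' @export
fit_egm11r <- function(x, r) {
  gs <- as_grey_series(x, min_length = 4L)
  design <- build_design(gs, r)
  coef <- grey_least_squares(design)
  delta <- derived_params(coef[["a"]], coef[["b"]])
  resp <- time_response(delta[["delta1"]], delta[["delta2"]],
                        gs$values[1L], gs$n)
  fitted_full <- fractional_difference(resp, r)
  new_grey_fit("EGM(1,1,r)", gs, r, coef,
               list(delta = delta), fitted_full)
}

#' Fit the classic even grey model GM(1,1)
#'
#' First-order accumulation, least squares on `x^(0)(k) + a z^(1)(k) = b`,
#' and the continuous (whitenization) time response
#' `x^(0)-hat(k) = (1 - e^a)(x^(0)(1) - b/a) e^(-a(k-1))`. The estimated
#' (a, b) coincide with `fit_egm11r(x, r = 1)`; the fitted values differ
#' because the response is the exponential solution of the whitenization
#' ODE rather than the discrete delta-recurrence.
#'
#' @inheritParams fit_egm11r
#' @return A `grey_fit` (see [fit_egm11r()]); `r` is fixed at 1.
#' @export
fit_gm11 <- function(x) {
  gs <- as_grey_series(x, min_length = 4L)
  design <- build_design(gs, 1)
  coef <- grey_least_squares(design)
  a <- coef[["a"]]; b <- coef[["b"]]
  if (a == 0) {
    stop("degenerate development coefficient a = 0: the GM(1,1) time ",
         "response is undefined", call. = FALSE)
  }
  k <- seq_len(gs$n)
  fitted_full <- c(gs$values[1L],
                   (1 - exp(a)) * (gs$values[1L] - b / a) *
                     exp(-a * (k[-1L] - 1)))
  new_grey_fit("GM(1,1)", gs, 1, coef, list(), fitted_full)
}

#' Fit the discrete grey model DGM(1,1)
#'
#' The standard discrete form: least squares on the 1-AGO recurrence
#' `x^(1)(k) = beta1 x^(1)(k-1) + beta2`, closed-form accumulated response
#' `x^(1)-hat(k) = beta1^(k-1)(x^(0)(1) - beta2/(1-beta1)) +
#' beta2/(1-beta1)`, and simulated originals by first difference.
#'
#' @inheritParams fit_egm11r
#' @return A `grey_fit`; `coef` holds `beta1`, `beta2`.
#' @export
fit_dgm11 <- function(x) {
  gs <- as_grey_series(x, min_length = 4L)
  x1 <- cumsum(gs$values)
  n <- gs$n
  B <- cbind(x1[-n], 1)
  qrB <- qr(B)
  if (qrB$rank < 2L) {
    stop("rank-deficient DGM(1,1) system", call. = FALSE)
  }
  beta <- stats::setNames(as.numeric(qr.coef(qrB, x1[-1L])),
                          c("beta1", "beta2"))
  b1 <- beta[["beta1"]]; b2 <- beta[["beta2"]]
  if (b1 == 1) {
    stop("degenerate DGM(1,1): beta1 = 1 has no fixed point", call. = FALSE)
  }
  k <- seq_len(n)
  x1hat <- b1^(k - 1) * (gs$values[1L] - b2 / (1 - b1)) + b2 / (1 - b1)
  fitted_full <- c(gs$values[1L], diff(x1hat))
  new_grey_fit("DGM(1,1)", gs, 1, beta, list(), fitted_full)
}

#' Forecast from a fitted grey model
#'
#' Extends the fitted model `h` steps past the training window, without
#' refitting. For EGM(1,1,r) the delta-recurrence is continued to k = n+h
#' and the inverse fractional difference is applied to the full extended
#' accumulated sequence; for GM(1,1) and DGM(1,1) the closed-form responses
#' are evaluated at the future indices.
#'
#' @param object A `grey_fit`.
#' @param h Forecast horizon (nonnegative integer); `h = 0` gives an empty
#'   result.
#' @param ... Unused.
#'
#' @return Numeric vector of `h` forecasts, named by period label.
#' @examples
#' fit <- fit_egm11r(beef_fixture()$train, r = 0.436213)
#' round(predict(fit, h = 1), 2)   # 2016: 740.59
#' @export
predict.grey_fit <- function(object, h = 1, ...) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h < 0 ||
      h != floor(h)) {
    stop("forecast horizon h must be a nonnegative integer", call. = FALSE)
  }
  h <- as.integer(h)
  gs <- object$series
  step <- if (gs$n > 1) gs$labels[2L] - gs$labels[1L] else 1
  labels_out <- gs$labels[gs$n] + step * seq_len(h)
  if (h == 0L) return(stats::setNames(numeric(0), character(0)))
  n <- gs$n
  K <- n + h
  out <- switch(
    object$model,
    "EGM(1,1,r)" = {
      resp <- time_response(object$delta[["delta1"]],
                            object$delta[["delta2"]],
                            gs$values[1L], K)
      fractional_difference(resp, object$r)[(n + 1L):K]
    },
    "GM(1,1)" = {
      a <- object$coef[["a"]]; b <- object$coef[["b"]]
      k <- (n + 1L):K
      (1 - exp(a)) * (gs$values[1L] - b / a) * exp(-a * (k - 1))
    },
    "DGM(1,1)" = {
      b1 <- object$coef[["beta1"]]; b2 <- object$coef[["beta2"]]
      k <- n:K
      x1hat <- b1^(k - 1) * (gs$values[1L] - b2 / (1 - b1)) +
        b2 / (1 - b1)
      diff(x1hat)
    },
    stop("unknown model: ", object$model, call. = FALSE))
  stats::setNames(out, labels_out)
}

#' @export
print.grey_fit <- function(x, digits = 2, ...) {
  cat(x$model, " fit on ", x$series$n, " points (",
      x$series$labels[1], "..", x$series$labels[x$series$n], ")\n",
      sep = "")
  cat("  order r:", format(x$r, digits = 7), "\n")
  cat("  coefficients:",
      paste(names(x$coef), format(x$coef, digits = 7), sep = " = ",
            collapse = ", "), "\n")
  if (!is.null(x$delta)) {
    cat("  recurrence:",
        paste(names(x$delta), format(x$delta, digits = 7), sep = " = ",
              collapse = ", "), "\n")
  }
  cat("  MRSPE:", format(round(100 * x$mrspe, digits), nsmall = digits),
      "%\n")
  invisible(x)
}

#' @export
summary.grey_fit <- function(object, ...) {
  gs <- object$series
  data.frame(
    label = gs$labels[-1L],
    actual = gs$values[-1L],
    fitted = object$fitted,
    residual = object$residuals,
    rspe_pct = 100 * object$rspe
  )
}
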