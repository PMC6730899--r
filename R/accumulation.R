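#' Fractional accumulation weights
#'
#' Generalized-binomial weights of the r-order accumulation generation
#' operator (r-AGO): `w_j = Gamma(r + j) / (Gamma(j + 1) * Gamma(r))`,
#' computed by the multiplicative recurrence `w_0 = 1`,
#' `w_j = w_{j-1} * (r + j - 1) / j`. The recurrence avoids evaluating the
#' Gamma function near its poles (for integer `r` the direct formula hits
#' `Gamma` at nonpositive arguments where the true coefficient is 0) and is
#' exact for integer orders: at `r = 1` all weights are 1, at `r = 2` they
#' are `1, 2, 3, ...`.
#'
#' @param r Accumulation order, a positive real.
#' @param m Maximum lag (nonnegative integer); `m + 1` weights are returned.
#'
#' @return Numeric vector `w_0, ..., w_m`, all nonnegative for `r > 0`.
#' @examples
#' ago_weights(0.5, 2)   # 1, 0.5, 0.375
#' ago_weights(2, 2)     # 1, 2, 3
#' @export
ago_weights <- function(r, m) {
  check_order(r)
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 ||
      m != floor(m)) {
    stop("m must be a nonnegative integer", call. = FALSE)
  }
  m <- as.integer(m)
  w <- numeric(m + 1L)
  w[1L] <- 1
  if (m > 0L) {
    for (j in seq_len(m)) w[j + 1L] <- w[j] * (r + j - 1) / j
  }
  w
}

# Signed weights of the inverse operator (fractional difference):
# d_0 = 1, d_i = d_{i-1} * (i - 1 - r) / i, i.e. (-1)^i * C(r, i) extended
# past i > r, where the recurrence vanishes identically for integer r.
difference_weights <- function(r, m) {
  check_order(r)
  m <- as.integer(m)
  d <- numeric(m + 1L)
  d[1L] <- 1
  if (m > 0L) {
    for (i in seq_len(m)) d[i + 1L] <- d[i] * (i - 1 - r) / i
  }
  d
}

check_order <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || !is.finite(r) ||
      r <= 0) {
    stop("accumulation order r must be a positive finite number",
         call. = FALSE)
  }
  invisible(r)
}

#' Fractional-order accumulation (r-AGO)
#'
#' Maps the original sequence X^(0) to its r-order accumulation
#' X^(r), `x^(r)(k) = sum_{i=1..k} w_{k-i} x^(0)(i)` with the
#' generalized-binomial weights of [ago_weights()]. At `r = 1` this is the
#' running sum; integer orders equal the running sum applied that many
#' times. The first accumulated value always equals the first original
#' value. For `r >= 1` the result is nondecreasing on positive input; for
#' `0 < r < 1` it need not be (the weights decay with lag, so a large
#' early value can outweigh later ones).
#'
#' @param x Numeric vector or [grey_series()]; nonnegative original values.
#' @param r Accumulation order, positive real.
#'
#' @return Numeric vector of the same length; the r-accumulated series.
#' @seealso [fractional_difference()] for the exact inverse.
#' @examples
#' fractional_accumulate(c(1, 2, 3), 1)   # 1 3 6
#' fractional_accumulate(c(1, 1, 1), 2)   # 1 3 6
#' @export
fractional_accumulate <- function(x, r) {
  if (inherits(x, "grey_series")) x <- x$values
  x <- as.numeric(x)
  n <- length(x)
  if (n == 0L) stop("cannot accumulate an empty series", call. = FALSE)
  w <- ago_weights(r, n - 1L)
  vapply(seq_len(n),
         function(k) sum(w[seq_len(k)] * x[k:1L]),
         numeric(1))
}

#' Inverse fractional accumulation (fractional difference)
#'
#' Restores the original sequence from an r-accumulated one:
#' `x^(0)(k) = sum_{i=0..k-1} d_i x^(r)(k - i)` with alternating
#' generalized-binomial weights `d_i = (-1)^i C(r, i)` computed by a stable
#' recurrence (see [ago_weights()] for why no Gamma call is made). It is the
#' exact inverse of [fractional_accumulate()] at the same order; at `r = 1`
#' it is the first difference with the first value passed through.
#'
#' @param xr Numeric vector; an r-accumulated series.
#' @param r The accumulation order that produced `xr`.
#'
#' @return Numeric vector of the same length; the de-accumulated series.
#' @examples
#' fractional_difference(c(1, 3, 6), 1)   # 1 2 3
#' x <- c(3, 1, 4, 1, 5)
#' fractional_difference(fractional_accumulate(x, 0.7), 0.7)  # x again
#' @export
fractional_difference <- function(xr, r) {
  xr <- as.numeric(xr)
  n <- length(xr)
  if (n == 0L) stop("cannot difference an empty series", call. = FALSE)
  d <- difference_weights(r, n - 1L)
  vapply(seq_len(n),
         function(k) sum(d[seq_len(k)] * xr[k:1L]),
         numeric(1))
}

#' Mean generated sequence of consecutive neighbors
#'
#' The background values Z of the grey difference equation:
#' `z(k) = 0.5 * (x(k) + x(k - 1))` for k = 2..n, usually applied to an
#' accumulated series.
#'
#' @param xr Numeric vector of length at least 2.
#'
#' @return Numeric vector of length `length(xr) - 1`, entries for k = 2..n.
#' @examples
#' mean_sequence(c(1, 3, 6))   # 2, 4.5
#' @export
mean_sequence <- function(xr) {
  xr <- as.numeric(xr)
  n <- length(xr)
  if (n < 2L) {
    stop("mean sequence needs at least 2 values", call. = FALSE)
  }
  0.5 * (xr[-1L] + xr[-n])
}
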