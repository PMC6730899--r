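#' Generate a synthetic series from the EGM(1,1,r) recurrence
#'
#' Manufactures ground-truth data for parameter-recovery studies: builds
#' the accumulated sequence by the delta-recurrence
#' `x^(r)(k) = delta1 x^(r)(k-1) + delta2` from `first_value`, inverts it
#' with the fractional difference, then (optionally) multiplies by
#' log-normal noise `exp(N(0, noise_sd))`. With `noise_sd = 0` the output
#' satisfies the grey difference equation exactly, so
#' [fit_egm11r()] at the true `r` recovers `(a, b)` to machine precision
#' and fits with zero error.
#'
#' @param a,b Generating development coefficient and grey input.
#' @param r Generating accumulation order (> 0).
#' @param first_value First value of the series (> 0).
#' @param n Series length (>= 4).
#' @param noise_sd Standard deviation of the multiplicative log-normal
#'   noise; 0 for an exact recurrence series.
#' @param seed Integer seed used when `noise_sd > 0`.
#'
#' @return A [grey_series()] with labels 1..n.
#' @examples
#' x <- generate_synthetic(a = 0.05, b = 10, r = 0.8, first_value = 5,
#'                         n = 20)
#' fit_egm11r(x, 0.8)$coef   # recovers a = 0.05, b = 10
#' @export
generate_synthetic <- function(a, b, r, first_value, n,
                               noise_sd = 0, seed = 1L) {
  check_order(r)
  if (!is.numeric(n) || n < 4 || n != floor(n)) {
    stop("n must be an integer >= 4", call. = FALSE)
  }
  if (first_value <= 0) {
    stop("first_value must be positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  n <- as.integer(n)
  delta <- derived_params(a, b)
  resp <- time_response(delta[["delta1"]], delta[["delta2"]],
                        first_value, n)
  values <- fractional_difference(resp, r)
  if (any(values < 0)) {
    stop("generated series goes negative at position(s) ",
         paste(which(values < 0), collapse = ", "),
         "; use a smaller |a| or a larger first_value", call. = FALSE)
  }
  if (noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    values <- values * exp(stats::rnorm(n, 0, noise_sd))
  }
  grey_series(values)
}
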