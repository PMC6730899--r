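# Shared helpers: independent oracles and random-case generators.

# Independent oracle for integer-order accumulation: repeated running sums.
cumsum_k <- function(x, times) {
  for (i in seq_len(times)) x <- cumsum(x)
  x
}

# Direct log-Gamma evaluation of the r-AGO weights (oracle for the
# multiplicative recurrence; valid for non-integer r).
gamma_weights <- function(r, m) {
  j <- 0:m
  exp(lgamma(r + j) - lgamma(j + 1) - lgamma(r))
}

# Random nonnegative series for property-style loops.
rand_series <- function(n, seed) {
  set.seed(seed)
  round(stats::runif(n, 0.5, 100), 3)
}

# Printed reference values of the beef case study, used across test files.
beef_egm_fitted <- c(199.22, 252.20, 296.70, 335.58, 370.35, 401.92,
                     430.90, 457.71, 482.67, 506.02, 527.96, 548.63,
                     568.16, 586.65, 604.20, 620.88, 636.75, 651.89,
                     666.32, 680.11, 693.29, 705.9, 717.96, 729.52)
beef_gm_fitted <- c(335.28, 347.89, 360.98, 374.56, 388.65, 403.27,
                    418.43, 434.17, 450.50, 467.45, 485.03, 503.28,
                    522.21, 541.85, 562.23, 583.38, 605.32, 628.09,
                    651.72, 676.23, 701.67, 728.06, 755.44, 783.86)
beef_dgm_fitted <- c(335.9, 348.5, 361.57, 375.13, 389.2, 403.79,
                     418.94, 434.65, 450.95, 467.86, 485.41, 503.62,
                     522.5, 542.1, 562.43, 583.52, 605.41, 628.11,
                     651.67, 676.11, 701.47, 727.78, 755.07, 783.39)
beef_r <- 0.436213
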