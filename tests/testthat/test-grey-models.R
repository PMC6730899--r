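test_that("design system has the documented shape and reduces to the classic one at r = 1", {
  beef <- beef_fixture()
  d <- build_design(beef$train, beef_r)
  expect_equal(nrow(d$B), 24)
  expect_equal(length(d$Y), 24)
  expect_true(all(d$B[, 2] == 1))
  # Y(2) by direct substitution: (r - 1) x(1) + x(2)
  expect_equal(d$Y[1], (beef_r - 1) * 131.3 + 172.9)
  # at r = 1 the response is the original series itself
  d1 <- build_design(beef$train, 1)
  expect_equal(d1$Y, beef$train$values[-1])
  expect_error(build_design(c(1, 2, 3), 1), "at least 4")
})

test_that("least squares recovers the published beef parameters and exact synthetic ones", {
  beef <- beef_fixture()
  coef <- grey_least_squares(build_design(beef$train, beef_r))
  expect_equal(unname(round(coef["a"], 6)), 0.011767)
  expect_equal(unname(round(coef["b"], 6)), 127.481416)  # see vignette on b
  # a generator series built from the recurrence is fitted exactly
  x <- generate_synthetic(a = 0.05, b = 10, r = 0.8, first_value = 5,
                          n = 20)
  coef2 <- grey_least_squares(build_design(x, 0.8))
  expect_equal(unname(coef2["a"]), 0.05, tolerance = 1e-8)
  expect_equal(unname(coef2["b"]), 10, tolerance = 1e-8)
  # rank deficiency: duplicated rows only
  expect_error(
    grey_least_squares(list(Y = c(1, 1), B = rbind(c(-2, 1), c(-2, 1)))),
    "rank-deficient")
})

test_that("recurrence coefficients are the exact algebraic map of (a, b)", {
  d <- derived_params(0.011767, 127.481369)
  expect_lt(abs(d[["delta1"]] - 0.988301), 1e-6)
  expect_lt(abs(d[["delta2"]] - 126.735694), 1e-4)
  expect_equal(derived_params(0, 5), c(delta1 = 1, delta2 = 5))
  expect_equal(derived_params(2, 0), c(delta1 = 0, delta2 = 0))
  expect_error(derived_params(-2, 1), "a = -2")
})

test_that("time response iterates the delta recurrence from the anchor", {
  expect_equal(time_response(0.9, 2, 10, 1), 10)
  expect_equal(time_response(0.988301, 126.735694, 131.3, 2)[2],
               256.4996, tolerance = 5e-4)
  # degenerate delta1 = 1: arithmetic progression
  expect_equal(time_response(1, 3, 2, 5), 2 + 3 * (0:4))
  # recurrence agrees with the closed geometric form
  d1 <- 0.97; d2 <- 5; f <- 40
  k <- 1:12
  closed <- d1^(k - 1) * f + d2 * ifelse(k > 1, (1 - d1^(k - 1)) / (1 - d1), 0)
  expect_equal(time_response(d1, d2, f, 12), closed)
})

test_that("EGM(1,1,r) fit reproduces the case-study table and fits its own process exactly", {
  beef <- beef_fixture()
  fit <- fit_egm11r(beef$train, beef_r)
  expect_s3_class(fit, "grey_fit")
  expect_length(fit$fitted, 24)
  expect_lt(abs(fit$fitted[1] - 199.22), 0.005)   # 1992
  expect_lt(abs(fit$fitted[22] - 705.9), 0.005)   # 2013
  expect_lt(abs(100 * fit$mrspe - 5.35), 0.01)
  expect_equal(fit$mrspe, mean(fit$rspe))
  # noise-free synthetic recurrence data: essentially zero error
  x <- generate_synthetic(a = -0.02, b = 8, r = 1.3, first_value = 12,
                          n = 16)
  expect_lt(fit_egm11r(x, 1.3)$mrspe, 1e-6)
  # determinism: bit-identical refits
  expect_identical(fit_egm11r(beef$train, beef_r), fit)
})

test_that("EGM at r = 1 shares the GM(1,1) parameters but not its fitted values", {
  beef <- beef_fixture()
  e1 <- fit_egm11r(beef$train, 1)
  gm <- fit_gm11(beef$train)
  expect_equal(e1$coef, gm$coef, tolerance = 1e-12)
  # discrete recurrence vs continuous exponential response: visibly different
  expect_gt(max(abs(e1$fitted - gm$fitted)), 0.1)
})

test_that("GM(1,1) and DGM(1,1) reproduce their case-study columns", {
  beef <- beef_fixture()
  gm <- fit_gm11(beef$train)
  expect_lt(abs(gm$fitted[1] - 335.28), 0.005)
  expect_lt(abs(100 * gm$mrspe - 12.26), 0.01)
  dgm <- fit_dgm11(beef$train)
  expect_lt(abs(dgm$fitted[1] - 335.9), 0.005)
  expect_lt(abs(100 * dgm$mrspe - 12.25), 0.01)
})

test_that("forecasts extend the fitted model without refitting", {
  beef <- beef_fixture()
  fit <- fit_egm11r(beef$train, beef_r)
  expect_length(predict(fit, 0), 0)
  expect_error(predict(fit, -1), "nonnegative")
  f1 <- predict(fit, 1)
  expect_lt(abs(unname(f1) - 740.59), 0.005)
  expect_equal(names(f1), "2016")
  f10 <- predict(fit, 10)
  expect_true(all(f10 > 0))
  # the h-step forecast is a prefix-stable extension
  expect_equal(f10[1], f1)
  gm3 <- predict(fit_gm11(beef$train), 3)
  expect_true(all(abs(gm3 - c(813.34, 843.94, 875.68)) <= 0.005))
  dgm3 <- predict(fit_dgm11(beef$train), 3)
  expect_true(all(abs(dgm3 - c(812.77, 843.25, 874.88)) <= 0.005))
})

test_that("degenerate inputs are rejected with specific errors", {
  expect_error(fit_egm11r(c(-1, 2, 3, 4), 0.5), "nonnegative")
  expect_error(fit_egm11r(c(1, NA, 3, 4), 0.5), "missing")
  expect_error(grey_series(c(1, 2), labels = c(2, 1)), "increasing")
  expect_error(grey_series(c(1, 2, 3), labels = c(1, 2, 4)),
               "constant step")
})
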