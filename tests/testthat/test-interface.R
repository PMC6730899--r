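test_that("the packaged case-study fixture is exactly the printed data", {
  beef <- beef_fixture()
  expect_equal(beef$train$n, 25)
  expect_identical(beef$train$values[1], 131.3)
  expect_identical(beef$train$values[25], 749.6)
  expect_identical(beef$train$labels, as.numeric(1991:2015))
  expect_identical(beef$holdout, c(767, 794, 814))
})

test_that("read_series handles CSV/TSV, headers and validation", {
  path <- system.file("extdata", "beef_consumption.csv", package = "egmr")
  gs <- read_series(path)
  beef <- beef_fixture()
  expect_equal(gs$values, beef$train$values)
  expect_equal(gs$labels, beef$train$labels)

  # headerless TSV
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("1\t4.5", "2\t5.5", "3\t6.5", "4\t7.5"), tsv)
  expect_equal(read_series(tsv)$values, c(4.5, 5.5, 6.5, 7.5))

  # single column gets synthetic labels 1..n
  one <- tempfile(fileext = ".csv")
  writeLines(c("10", "11", "12", "13"), one)
  gs1 <- read_series(one)
  expect_equal(gs1$labels, as.numeric(1:4))

  # row-numbered rejection of bad cells
  bad <- tempfile(fileext = ".csv")
  writeLines(c("year,value", "1991,5", "1992,-5", "1993,6"), bad)
  expect_error(read_series(bad), "row.*3")
  nonnum <- tempfile(fileext = ".csv")
  writeLines(c("1991,5", "1992,abc", "1993,6"), nonnum)
  expect_error(read_series(nonnum), "row")
  expect_error(read_series(tempfile()), "not found")
})

test_that("the synthetic generator manufactures exact recurrence data", {
  # at the case-study parameters it reproduces the fitted sequence
  x <- generate_synthetic(a = 0.011767, b = 127.481369, r = beef_r,
                          first_value = 131.3, n = 25)
  expect_lt(abs(x$values[2] - 199.22), 0.005)
  # noise-free data are fitted back exactly
  fit <- fit_egm11r(x, beef_r)
  expect_equal(unname(fit$coef["a"]), 0.011767, tolerance = 1e-8)
  expect_equal(unname(fit$coef["b"]), 127.481369, tolerance = 1e-8)
  expect_lt(fit$mrspe, 1e-9)
  # seed determinism of the noisy path
  n1 <- generate_synthetic(0.02, 5, 0.9, 3, 12, noise_sd = 0.1, seed = 5)
  n2 <- generate_synthetic(0.02, 5, 0.9, 3, 12, noise_sd = 0.1, seed = 5)
  n3 <- generate_synthetic(0.02, 5, 0.9, 3, 12, noise_sd = 0.1, seed = 6)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, n3$values))
  # a development coefficient too large for the anchor goes negative
  expect_error(generate_synthetic(0.9, 0.1, 0.5, 5, 6), "negative")
})

test_that("write_report renders the comparison, forecasts and unrounded summary", {
  beef <- beef_fixture()
  cmp <- compare_models(beef$train, r = beef_r)
  outdir <- file.path(tempdir(), "egmr-report")
  files <- write_report(cmp, outdir, horizon = 3, holdout = beef$holdout)
  expect_true(all(file.exists(files)))

  tab <- utils::read.csv(files[["comparison"]])
  expect_equal(nrow(tab), 25)  # 24 periods + MRSPE row
  mrspe_row <- tab[tab$label == "MRSPE(%)", ]
  expect_equal(mrspe_row$egm11r_rspe_pct, 5.35)
  expect_equal(mrspe_row$gm11_rspe_pct, 12.26)
  expect_equal(mrspe_row$dgm11_rspe_pct, 12.25)

  fc <- utils::read.csv(files[["forecast"]])
  expect_equal(fc$label, 2016:2018)
  expect_equal(fc$egm11r_forecast[1], 740.59)
  expect_equal(fc$gm11_forecast, c(813.34, 843.94, 875.68))

  summ <- jsonlite::read_json(files[["summary"]], simplifyVector = TRUE)
  expect_equal(summ$models$egm11r$coef$a, unname(cmp$fits$egm11r$coef["a"]))
  expect_equal(summ$models$egm11r$mrspe, cmp$fits$egm11r$mrspe)
  expect_true(summ$smoothness$quasi_smooth)
  expect_equal(summ$holdout_mrpe$gm11, 0.0664, tolerance = 0.001)

  # an empty result set is an error
  empty <- structure(list(fits = list(), table = NULL,
                          series = beef$train),
                     class = "grey_comparison")
  expect_error(write_report(empty, outdir), "no fitted models")
})

test_that("compare_models selects the order automatically when asked", {
  beef <- beef_fixture()
  cmp <- compare_models(beef$train, models = "egm11r", r = "auto-grid")
  expect_false(is.null(cmp$order_search))
  expect_identical(cmp$fits$egm11r$r, cmp$order_search$r_opt)
  expect_lte(cmp$order_search$objective, objective_mrspe(beef$train, 1))
})

test_that("the CLI subcommands drive the same pipeline", {
  # smoothness check on the packaged fixture passes
  expect_output(status <- egmr:::cli_run(c("check", "--fixture", "beef")),
                "PASS")
  expect_equal(status, 0L)

  outdir <- file.path(tempdir(), "egmr-cli")
  expect_output(
    egmr:::cli_run(c("compare", "--fixture", "beef",
                     "--order", "0.436213", "--forecast", "3",
                     "--outdir", outdir)),
    "EGM\\(1,1,r\\)")
  expect_true(file.exists(file.path(outdir, "comparison.csv")))
  expect_true(file.exists(file.path(outdir, "forecast.csv")))
  expect_true(file.exists(file.path(outdir, "summary.json")))

  simdir <- file.path(tempdir(), "egmr-sim")
  expect_output(
    egmr:::cli_run(c("simulate", "--a", "0.02", "--b", "5", "--r", "0.8",
                     "--first", "3", "--n", "12", "--outdir", simdir)),
    "synthetic.csv")
  sim <- utils::read.csv(file.path(simdir, "synthetic.csv"))
  expect_equal(nrow(sim), 12)
  expect_error(egmr:::cli_run(c("explode")), "unknown subcommand")
  expect_error(egmr:::cli_run(c("fit")), "--input")
})
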