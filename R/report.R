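#' Fit several grey models side by side
#'
#' Fits any subset of EGM(1,1,r), GM(1,1) and DGM(1,1) to the same series
#' and assembles a comparison in the conventional layout: one row per
#' period with the actual value and, per model, the simulated value and
#' its relative simulation percentage error, plus an MRSPE summary row
#' when rendered by [write_report()].
#'
#' @param x Numeric vector or [grey_series()].
#' @param models Character subset of `c("egm11r", "gm11", "dgm11")`.
#' @param r Accumulation order for EGM(1,1,r): a number, or `"auto-grid"` /
#'   `"auto-pso"` to select it by [grid_search_order()] /
#'   [optimize_order_pso()].
#' @param seed Seed forwarded to the PSO when `r = "auto-pso"`.
#'
#' @return A list of class `grey_comparison`: `fits` (named list of
#'   `grey_fit`), `table` (data frame), `order_search` (when r was
#'   selected automatically, else NULL).
#' @examples
#' cmp <- compare_models(beef_fixture()$train, r = 0.436213)
#' round(100 * vapply(cmp$fits, function(f) f$mrspe, numeric(1)), 2)
#' @export
compare_models <- function(x, models = c("egm11r", "gm11", "dgm11"),
                           r = "auto-grid", seed = 1L) {
  gs <- as_grey_series(x, min_length = 4L)
  models <- match.arg(models, several.ok = TRUE)
  search <- NULL
  if ("egm11r" %in% models && is.character(r)) {
    search <- switch(r,
                     "auto-grid" = grid_search_order(gs),
                     "auto-pso" = optimize_order_pso(
                       gs, pso_config(seed = seed)),
                     stop("r must be a number, \"auto-grid\" or ",
                          "\"auto-pso\"", call. = FALSE))
    r <- search$r_opt
  }
  fits <- list()
  if ("egm11r" %in% models) fits[["egm11r"]] <- fit_egm11r(gs, r)
  if ("gm11" %in% models) fits[["gm11"]] <- fit_gm11(gs)
  if ("dgm11" %in% models) fits[["dgm11"]] <- fit_dgm11(gs)

  tab <- data.frame(label = gs$labels[-1L], actual = gs$values[-1L])
  for (nm in names(fits)) {
    tab[[paste0(nm, "_fitted")]] <- fits[[nm]]$fitted
    tab[[paste0(nm, "_rspe_pct")]] <- 100 * fits[[nm]]$rspe
  }
  structure(list(fits = fits, table = tab, order_search = search,
                 series = gs),
            class = "grey_comparison")
}

#' @export
print.grey_comparison <- function(x, digits = 2, ...) {
  cat("Grey model comparison on", x$series$n, "points\n")
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    cat(sprintf("  %-11s MRSPE %6s%%", f$model,
                format(round(100 * f$mrspe, digits), nsmall = digits)))
    if (nm == "egm11r") cat("  (r =", format(f$r, digits = 6), ")")
    cat("\n")
  }
  invisible(x)
}

#' Write comparison, forecast and summary files for a model run
#'
#' Renders a [compare_models()] result to an output directory:
#' `comparison.csv` (per-period actual, fitted and RSPE columns with a
#' final MRSPE row, values rounded for display), `forecast.csv` (per-model
#' forecasts labeled by period, when `horizon > 0`), `summary.json`
#' (unrounded parameters, errors, optional holdout evaluation, smoothness
#' report and the configuration echo) and `run.log` (plain-text record of
#' the decisions taken). Percentages are fractions internally and scaled
#' to percent only in these rendered files.
#'
#' @param comparison A `grey_comparison` from [compare_models()].
#' @param outdir Output directory, created if needed.
#' @param horizon Forecast horizon (>= 0).
#' @param holdout Optional numeric vector of withheld actuals immediately
#'   following the training window; when supplied, the first
#'   `length(holdout)` forecasts of each model are scored by
#'   [holdout_mrpe()].
#' @param digits Display rounding for the CSV tables (the JSON summary is
#'   never rounded).
#'
#' @return Invisibly, the named character vector of files written.
#' @export
write_report <- function(comparison, outdir, horizon = 0, holdout = NULL,
                         digits = 2) {
  stopifnot(inherits(comparison, "grey_comparison"))
  if (length(comparison$fits) == 0L) {
    stop("no fitted models to report", call. = FALSE)
  }
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  horizon <- max(as.integer(horizon), if (is.null(holdout)) 0L else
    length(holdout))
  files <- c()

  tab <- comparison$table
  disp <- tab
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, digits = digits)
  mrspe_row <- disp[1, ]
  mrspe_row[] <- NA
  mrspe_row$label <- "MRSPE(%)"
  for (nm in names(comparison$fits)) {
    mrspe_row[[paste0(nm, "_rspe_pct")]] <-
      round(100 * comparison$fits[[nm]]$mrspe, digits)
  }
  disp$label <- as.character(disp$label)
  comparison_path <- file.path(outdir, "comparison.csv")
  utils::write.csv(rbind(disp, mrspe_row), comparison_path,
                   row.names = FALSE, na = "")
  files["comparison"] <- comparison_path

  forecasts <- NULL
  if (horizon > 0L) {
    forecasts <- lapply(comparison$fits, predict, h = horizon)
    ftab <- data.frame(label = as.numeric(names(forecasts[[1L]])))
    for (nm in names(forecasts)) {
      ftab[[paste0(nm, "_forecast")]] <- round(unname(forecasts[[nm]]),
                                               digits)
    }
    forecast_path <- file.path(outdir, "forecast.csv")
    utils::write.csv(ftab, forecast_path, row.names = FALSE)
    files["forecast"] <- forecast_path
  }

  smooth <- quasi_smooth_check(comparison$series)
  summary <- list(
    n = comparison$series$n,
    labels = comparison$series$labels,
    models = lapply(comparison$fits, function(f) {
      out <- list(model = f$model, r = f$r, coef = as.list(f$coef),
                  mrspe = f$mrspe, fitted = f$fitted)
      if (!is.null(f$delta)) out$delta <- as.list(f$delta)
      out
    }),
    smoothness = list(rho = unname(smooth$rho),
                      lambda = unname(smooth$lambda),
                      epsilon = smooth$epsilon,
                      quasi_smooth = smooth$quasi_smooth),
    order_search = if (!is.null(comparison$order_search)) {
      list(method = comparison$order_search$method,
           r_opt = comparison$order_search$r_opt,
           objective = comparison$order_search$objective)
    },
    config = list(horizon = horizon, digits = digits,
                  holdout = holdout)
  )
  if (!is.null(holdout)) {
    summary$holdout_mrpe <- lapply(forecasts, function(fc)
      holdout_mrpe(fc[seq_along(holdout)], holdout))
  }
  summary_path <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files["summary"] <- summary_path

  log_lines <- c(
    paste0("egmr run at ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("series: n = ", comparison$series$n, ", labels ",
           comparison$series$labels[1], "..",
           comparison$series$labels[comparison$series$n]),
    paste0("models: ", paste(names(comparison$fits), collapse = ", ")),
    if (!is.null(comparison$order_search)) {
      paste0("order policy: ", comparison$order_search$method,
             " search, r_opt = ",
             format(comparison$order_search$r_opt, digits = 7))
    } else if ("egm11r" %in% names(comparison$fits)) {
      paste0("order policy: fixed r = ",
             format(comparison$fits$egm11r$r, digits = 7))
    },
    paste0("quasi-smooth: ", smooth$quasi_smooth),
    paste0("horizon: ", horizon)
  )
  log_path <- file.path(outdir, "run.log")
  writeLines(log_lines, log_path)
  files["log"] <- log_path

  invisible(files)
}
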