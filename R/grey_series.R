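#' Construct a grey time series
#'
#' A `grey_series` is the original sequence X^(0) of grey-systems modeling:
#' an ordered, nonnegative numeric vector with regularly spaced period labels
#' (typically years). All model-fitting functions in the package take one.
#'
#' @param values Numeric vector of nonnegative observations.
#' @param labels Period labels, strictly increasing with a constant step
#'   (e.g. years). Defaults to `1:length(values)`.
#' @param min_length Minimum admissible length. Model fitting requires at
#'   least 4 points (the least-squares system needs two rows and the
#'   smoothness diagnostics start at the third point); the constructor itself
#'   only requires 1 so that partial series can be built and inspected.
#'
#' @return An object of class `grey_series`: a list with elements `labels`,
#'   `values` and `n`.
#' @examples
#' gs <- grey_series(c(131.3, 172.9, 218.4, 303.6), labels = 1991:1994)
#' gs$n
#' @export
grey_series <- function(values, labels = seq_along(values), min_length = 1L) {
  values <- as.numeric(values)
  if (length(values) < min_length) {
    stop("series has ", length(values), " value(s); at least ", min_length,
         " required", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("series contains missing values at position(s) ",
         paste(which(is.na(values)), collapse = ", "), call. = FALSE)
  }
  if (any(values < 0)) {
    stop("grey models require a nonnegative original sequence; negative ",
         "value at position(s) ", paste(which(values < 0), collapse = ", "),
         call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (length(labels) != length(values)) {
    stop("labels and values differ in length", call. = FALSE)
  }
  if (length(labels) > 1) {
    steps <- diff(labels)
    if (any(steps <= 0)) {
      stop("labels must be strictly increasing", call. = FALSE)
    }
    if (length(unique(steps)) > 1 &&
        max(steps) - min(steps) > 1e-8 * max(abs(labels))) {
      stop("labels must have a constant step", call. = FALSE)
    }
  }
  structure(list(labels = labels, values = values, n = length(values)),
            class = "grey_series")
}

#' @export
print.grey_series <- function(x, ...) {
  cat("Grey series: ", x$n, " points, ", x$labels[1], "..",
      x$labels[x$n], "\n", sep = "")
  print(stats::setNames(x$values, x$labels))
  invisible(x)
}

#' @export
as.numeric.grey_series <- function(x, ...) x$values

#' @export
length.grey_series <- function(x) x$n

# Coerce plain vectors at module boundaries; validates either way.
as_grey_series <- function(x, min_length = 1L) {
  if (inherits(x, "grey_series")) {
    grey_series(x$values, x$labels, min_length = min_length)
  } else {
    grey_series(x, min_length = min_length)
  }
}

#' Read a grey series from a delimited file
#'
#' Reads a one- or two-column CSV/TSV file into a [grey_series()]. With two
#' columns the first is taken as the period label and the second as the
#' value; with one column the rows are labeled 1..n. A header row is
#' auto-detected (first row non-numeric in the value column).
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`; default guesses from the file extension.
#'
#' @return A [grey_series()].
#' @examples
#' path <- system.file("extdata", "beef_consumption.csv", package = "egmr")
#' read_series(path)
#' @export
read_series <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- switch(format,
                csv = ",",
                tsv = "\t",
                auto = if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE))
                  "\t" else ",")
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           strip.white = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) > 2) {
    stop("expected 1 or 2 columns, found ", ncol(raw), call. = FALSE)
  }
  value_col <- ncol(raw)
  first_numeric <- !is.na(suppressWarnings(as.numeric(raw[1, value_col])))
  if (!first_numeric) raw <- raw[-1, , drop = FALSE]  # header row
  vals <- suppressWarnings(as.numeric(raw[[value_col]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals)) + as.integer(!first_numeric)
    stop("non-numeric or blank value in row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0) + as.integer(!first_numeric)
    stop("negative value in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (ncol(raw) == 2) {
    labs <- suppressWarnings(as.numeric(raw[[1]]))
    if (anyNA(labs)) {
      bad <- which(is.na(labs)) + as.integer(!first_numeric)
      stop("non-numeric label in row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    grey_series(vals, labs)
  } else {
    grey_series(vals)
  }
}

#' The China beef-consumption case study
#'
#' Total beef consumption in China, 1991-2015 (ten thousand tons), the
#' 25-point training series used throughout the package documentation, plus
#' the 2016-2018 actuals (767, 794, 814) withheld for forecast evaluation.
#'
#' @return A list with elements `train` (a 25-point [grey_series()] labeled
#'   1991-2015), `holdout` (numeric vector of the 2016-2018 actuals) and
#'   `holdout_labels` (2016:2018).
#' @examples
#' beef <- beef_fixture()
#' beef$train$values[1]   # 131.3
#' @export
beef_fixture <- function() {
  values <- c(131.3, 172.9, 218.4, 303.6, 405.1, 345.7, 432.3, 472.7,
              501.7, 510.0, 505.2, 521.4, 541.5, 556.6, 561.4, 569.2,
              606.5, 608.0, 634.0, 652.0, 644.9, 668.0, 705.2, 729.7,
              749.6)
  list(train = grey_series(values, labels = 1991:2015),
       holdout = c(767, 794, 814),
       holdout_labels = 2016:2018)
}
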