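#' Accuracy statistics for age predictions
#'
#' The four statistics used throughout this package to score an epigenetic
#' clock against chronological age, each taking the chronological ages `x`
#' and predicted ages `x_pred` as paired vectors:
#'
#' * `mad_error()` — mean absolute deviation, `mean(|x - x_pred|)`, years.
#'   (The mean, not the median; see `median_abs_error()` for the latter.)
#' * `see_error()` — standard error of the estimate,
#'   `sqrt(sum((x - x_pred)^2) / (n - 2))`, years; needs `n >= 3`.
#' * `pcp()` — percent of correct predictions: the percentage of samples
#'   whose absolute error is less than *or equal to* a threshold (boundary
#'   included).
#' * `r_squared()` — squared Pearson correlation between predicted and
#'   chronological age, bounded in \[0, 1\]. This is deliberately not the
#'   identity-line residual R², which can be negative for a biased clock.
#'
#' @param x Numeric vector of chronological ages (years).
#' @param x_pred Numeric vector of predicted ages, same length.
#' @param threshold Accuracy band in years for `pcp()`, strictly positive;
#'   conventional choices are 5, 7.5 and 10.
#' @return A single number: years for `mad_error()`/`see_error()`/
#'   `median_abs_error()`, percent in \[0, 100\] for `pcp()`, unitless in
#'   \[0, 1\] for `r_squared()`.
#' @name accuracy-metrics
NULL

check_paired <- function(x, x_pred, min_n = 1L) {
  if (length(x) != length(x_pred)) {
    stop("`x` and `x_pred` must have equal length", call. = FALSE)
  }
  if (length(x) < min_n) {
    stop("degenerate input: need at least ", min_n, " paired observation(s), ",
         "got ", length(x), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(x_pred))) {
    stop("all paired ages must be finite", call. = FALSE)
  }
  invisible(length(x))
}

#' @rdname accuracy-metrics
#' @export
mad_error <- function(x, x_pred) {
  check_paired(x, x_pred, 1L)
  mean(abs(x - x_pred))
}

#' @rdname accuracy-metrics
#' @export
see_error <- function(x, x_pred) {
  n <- check_paired(x, x_pred, 3L)
  sqrt(sum((x - x_pred)^2) / (n - 2))
}

#' @rdname accuracy-metrics
#' @export
pcp <- function(x, x_pred, threshold) {
  n <- check_paired(x, x_pred, 1L)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number of years",
         call. = FALSE)
  }
  100 * sum(abs(x - x_pred) <= threshold) / n
}

#' @rdname accuracy-metrics
#' @export
r_squared <- function(x, x_pred) {
  check_paired(x, x_pred, 2L)
  if (stats::sd(x) == 0 || stats::sd(x_pred) == 0) {
    stop("degenerate input: constant ages or constant predictions; ",
         "correlation undefined", call. = FALSE)
  }
  stats::cor(x, x_pred)^2
}

#' Delta ages
#'
#' Elementwise predicted minus chronological age, order preserved. Negative
#' values mean the clock reads "younger" than chronological age.
#'
#' @inheritParams accuracy-metrics
#' @return Numeric vector of years, same length as the input.
#' @export
delta_ages <- function(x, x_pred) {
  check_paired(x, x_pred, 1L)
  x_pred - x
}

#' Median absolute error
#'
#' Companion robust statistic to [mad_error()] (which is the *mean* absolute
#' deviation); named distinctly to avoid the mean/median ambiguity common in
#' the clock literature.
#'
#' @inheritParams accuracy-metrics
#' @export
median_abs_error <- function(x, x_pred) {
  check_paired(x, x_pred, 1L)
  stats::median(abs(x - x_pred))
}
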