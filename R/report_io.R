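#' Write an accuracy report as long-format CSV
#'
#' One row per (model, age_group, sex, metric, threshold): metrics `r2`,
#' `mad`, `see` carry an empty threshold, `pcp` one row per threshold.
#' Values are written at full double precision, so a write/read round trip
#' is lossless (well beyond the 6 significant digits the format guarantees).
#'
#' @param report An `accuracy_report` from [evaluate_strata()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.null(report) || nrow(report) == 0L) {
    stop("nothing to write: empty report", call. = FALSE)
  }
  thresholds <- attr(report, "thresholds")
  if (is.null(thresholds)) {
    thresholds <- as.numeric(sub("^pcp_", "",
                                 grep("^pcp_", names(report), value = TRUE)))
  }
  rows <- list()
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    base <- function(metric, threshold, value) {
      data.frame(model = r$model, age_group = r$age_group, sex = r$sex,
                 metric = metric, threshold = threshold, value = value,
                 n = r$n, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- base("r2", NA_real_, r$r2)
    rows[[length(rows) + 1L]] <- base("mad", NA_real_, r$mad)
    rows[[length(rows) + 1L]] <- base("see", NA_real_, r$see)
    for (th in thresholds) {
      rows[[length(rows) + 1L]] <- base("pcp", th, r[[pcp_col(th)]])
    }
  }
  long <- do.call(rbind, rows)
  long$threshold <- ifelse(is.na(long$threshold), "",
                           sprintf("%.17g", long$threshold))
  long$value <- ifelse(is.na(long$value), "",
                       sprintf("%.17g", long$value))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format accuracy report
#'
#' @param path CSV written by [write_report()].
#' @return Long data frame with columns `model`, `age_group`, `sex`,
#'   `metric`, `threshold`, `value`, `n`.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(model = "character",
                                        age_group = "character",
                                        sex = "character",
                                        metric = "character"))
  out$threshold <- suppressWarnings(as.numeric(out$threshold))
  out$value <- suppressWarnings(as.numeric(out$value))
  out
}
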