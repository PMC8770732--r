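#' Age-group schemes
#'
#' An ordered set of non-overlapping age bands with inclusive integer-year
#' bounds that together cover ages from 0 upward; ages beyond the last band's
#' upper bound fall into the last band.
#'
#' @param labels Character vector of band labels, in order.
#' @param lo,hi Integer-year inclusive bounds per band; `lo[1]` must be 0 and
#'   each band must start the year after the previous one ends.
#' @return A data frame of class `age_group_scheme`.
#' @export
age_group_scheme <- function(labels, lo, hi) {
  if (length(labels) != length(lo) || length(lo) != length(hi)) {
    stop("labels, lo and hi must have equal length", call. = FALSE)
  }
  if (anyDuplicated(labels)) stop("duplicate group labels", call. = FALSE)
  if (any(lo > hi)) stop("each group needs lo <= hi", call. = FALSE)
  if (lo[1] != 0) stop("the first group must start at age 0", call. = FALSE)
  if (length(lo) > 1 && any(lo[-1] != hi[-length(hi)] + 1)) {
    stop("groups must be contiguous and non-overlapping ",
         "(each lo = previous hi + 1)", call. = FALSE)
  }
  out <- data.frame(label = labels, lo = lo, hi = hi,
                    stringsAsFactors = FALSE)
  class(out) <- c("age_group_scheme", "data.frame")
  out
}

#' The young / adult / old scheme
#'
#' Young 0--17, adult 18--80, old 81 and above (nominally 81--101): the
#' grouping under which small-panel clocks are well calibrated in the adult
#' band and drift in the old band.
#'
#' @return An [age_group_scheme()].
#' @export
default_age_groups <- function() {
  age_group_scheme(c("young", "adult", "old"),
                   lo = c(0, 18, 81), hi = c(17, 80, 101))
}

#' Assign ages to groups
#'
#' Membership is by completed years (`floor(age)`); ages above the last
#' band's upper bound map to the last band.
#'
#' @param age Numeric vector of ages in years, all `>= 0`.
#' @param scheme An [age_group_scheme()].
#' @return Character vector of group labels.
#' @export
assign_age_group <- function(age, scheme = default_age_groups()) {
  if (any(!is.finite(age)) || any(age < 0)) {
    stop("validation error: ages must be finite and >= 0", call. = FALSE)
  }
  idx <- findInterval(floor(age), scheme$lo)
  scheme$label[idx]
}

#' Stratified accuracy evaluation
#'
#' Computes every accuracy statistic for each (age group x sex) stratum,
#' including the pooled `"all"` margin on both axes — the layout in which
#' clock-validation studies tabulate their results. Samples of unknown sex
#' contribute to pooled-sex strata only. Strata that exist in the data are
#' reported; statistics whose minimum n is not met are `NA` (SEE needs
#' n >= 3, R² needs n >= 2 with non-constant ages and predictions).
#'
#' @param records Prediction records from [predict_age()] (multiple models
#'   may be row-bound; each is evaluated separately).
#' @param scheme An [age_group_scheme()]; age groups are (re)assigned from
#'   `age` so records carrying labels from another scheme are handled.
#' @param thresholds PCP accuracy bands in years; default `c(5, 7.5, 10)`.
#' @return A data frame of class `accuracy_report`: one row per
#'   (model, age_group, sex) stratum with columns `n`, `r2`, `mad`, `see`
#'   and one `pcp_<threshold>` column per threshold.
#' @export
evaluate_strata <- function(records, scheme = default_age_groups(),
                            thresholds = c(5, 7.5, 10)) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("degenerate input: no prediction records", call. = FALSE)
  }
  if (is.null(records$model)) records$model <- "model"
  records$age_group <- assign_age_group(records$age, scheme)

  groups <- c(scheme$label, "all")
  sexes <- c("female", "male", "all")
  rows <- list()
  for (mod in unique(records$model)) {
    rm_ <- records[records$model == mod, ]
    for (g in groups) {
      in_g <- if (g == "all") rep(TRUE, nrow(rm_)) else rm_$age_group == g
      for (sx in sexes) {
        in_s <- if (sx == "all") rep(TRUE, nrow(rm_)) else rm_$sex == sx
        sub <- rm_[in_g & in_s, ]
        n <- nrow(sub)
        if (n == 0L) next
        r2 <- if (n >= 2 && stats::sd(sub$age) > 0 &&
                  stats::sd(sub$predicted_age) > 0) {
          r_squared(sub$age, sub$predicted_age)
        } else NA_real_
        see <- if (n >= 3) see_error(sub$age, sub$predicted_age) else NA_real_
        row <- data.frame(model = mod, age_group = g, sex = sx, n = n,
                          r2 = r2,
                          mad = mad_error(sub$age, sub$predicted_age),
                          see = see,
                          stringsAsFactors = FALSE)
        for (th in thresholds) {
          row[[pcp_col(th)]] <- pcp(sub$age, sub$predicted_age, th)
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("accuracy_report", "data.frame")
  out
}

pcp_col <- function(th) paste0("pcp_", sub("\\.?0+$", "", sprintf("%.2f", th)))

#' Compare delta age between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann--Whitney) test on delta age for two
#' independent groups of individuals: exact null distribution when the
#' combined sample size is at most 20 and there are no ties, otherwise the
#' normal approximation with midranks, tie-corrected variance and continuity
#' correction. A paired signed-rank variant is available for repeated
#' measurements of the same individuals.
#'
#' @param a,b Numeric vectors of delta ages, or prediction-record data frames
#'   (their `delta_age` column is used).
#' @param label_a,label_b Stratum labels for the output.
#' @param paired Use the signed-rank test for paired samples (default FALSE:
#'   independent groups).
#' @return One-row data frame: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic` (rank-sum U, or V when paired), `p_value`.
#' @export
compare_delta_age <- function(a, b, label_a = "a", label_b = "b",
                              paired = FALSE) {
  if (is.data.frame(a)) a <- a$delta_age
  if (is.data.frame(b)) b <- b$delta_age
  if (!length(a) || !length(b)) {
    stop("degenerate input: both groups must be non-empty", call. = FALSE)
  }
  exact <- !paired && (length(a) + length(b) <= 20) &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", paired = paired,
                       exact = exact, correct = TRUE)
  )
  data.frame(group_a = label_a, group_b = label_b,
             n_a = length(a), n_b = length(b),
             statistic = unname(wt$statistic),
             p_value = min(1, wt$p.value),
             stringsAsFactors = FALSE)
}

#' Error dynamics over cumulative age ranges
#'
#' How MAD or SEE changes as the evaluated age range widens: for each upper
#' bound t on a grid, the metric is computed over all records with age <= t,
#' the lower bound staying fixed at the cohort minimum. The early points
#' cover few samples and are noisy by construction; points below the
#' metric's minimum n (1 for MAD, 3 for SEE) are reported with `NA` value.
#'
#' @param records Prediction records from [predict_age()].
#' @param metric `"mad"` or `"see"`.
#' @param step Grid step in years (default 1). The final grid point is
#'   always the cohort maximum age, so the last value equals the global
#'   metric exactly.
#' @return A data frame of class `dynamics_curve`: `metric`, `t`, `n`,
#'   `value`.
#' @export
metric_dynamics <- function(records, metric = c("mad", "see"), step = 1) {
  metric <- match.arg(metric)
  if (is.null(records) || nrow(records) == 0L) {
    stop("degenerate input: no prediction records", call. = FALSE)
  }
  if (!is.numeric(step) || step <= 0) {
    stop("`step` must be a positive number of years", call. = FALSE)
  }
  lo <- min(records$age)
  hi <- max(records$age)
  grid <- seq(lo + step, hi, by = step)
  if (!length(grid) || grid[length(grid)] < hi) grid <- c(grid, hi)
  min_n <- if (metric == "mad") 1L else 3L
  fun <- if (metric == "mad") mad_error else see_error
  out <- do.call(rbind, lapply(grid, function(t) {
    sub <- records[records$age <= t, ]
    n <- nrow(sub)
    data.frame(metric = metric, t = t, n = n,
               value = if (n >= min_n) fun(sub$age, sub$predicted_age)
                       else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("dynamics_curve", "data.frame")
  out
}
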