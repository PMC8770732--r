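#' Predict epigenetic age for a cohort
#'
#' Applies one clock model to every sample and returns one prediction record
#' per usable sample: chronological age, predicted age, delta age
#' (predicted minus chronological) and age-group label. Samples missing a
#' methylation value at any site the model uses are excluded (with a logged
#' count), never imputed — imputation would bias the error metrics.
#'
#' @param model A [clock_model()].
#' @param samples Sample data frame (see [read_samples()]).
#' @param scheme Age-group scheme for labeling; default [default_age_groups()].
#' @return Data frame with columns `sample_id`, `sex`, `age`, `model`,
#'   `predicted_age`, `delta_age`, `age_group`, and — when the model declares
#'   a `valid_age_range` — a logical `outside_valid_range` flag (predictions
#'   are flagged, not clipped).
#' @export
predict_age <- function(model, samples, scheme = default_age_groups()) {
  stopifnot(inherits(model, "clock_model"))
  need <- model$terms$site_id
  absent <- setdiff(need, names(samples))
  if (length(absent)) {
    stop("missing methylation data: sample table has no column(s) ",
         paste(absent, collapse = ", "), " required by model '",
         model$model_id, "'", call. = FALSE)
  }
  m <- as.matrix(samples[need])
  usable <- stats::complete.cases(m)
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    message("model '", model$model_id, "': excluded ", n_drop,
            " sample(s) with missing methylation at required site(s)")
  }
  m <- m[usable, , drop = FALSE]
  powered <- sweep(m, 2, model$terms$power, `^`)
  pred <- model$intercept + drop(powered %*% model$terms$coefficient)

  out <- data.frame(
    sample_id = samples$sample_id[usable],
    sex = samples$sex[usable],
    age = samples$age[usable],
    model = model$model_id,
    predicted_age = pred,
    delta_age = pred - samples$age[usable],
    age_group = assign_age_group(samples$age[usable], scheme),
    stringsAsFactors = FALSE
  )
  if (!is.null(model$valid_age_range)) {
    out$outside_valid_range <- out$age < model$valid_age_range[1] |
      out$age > model$valid_age_range[2]
  }
  out
}

#' Regress methylation at one site on chronological age
#'
#' Ordinary least squares with methylation as the response and age as the
#' predictor (the reporting convention for age-drift slopes; the correlation
#' and its square are direction-invariant, the slope is not).
#'
#' @param samples Sample data frame.
#' @param site_id Panel site column to regress.
#' @return A one-row data frame of class `site_regression`: `site_id`,
#'   `slope` (percent methylation per year), `intercept` (percent at age 0),
#'   `pearson_r`, `r_squared` (= `pearson_r^2`), `n`.
#' @export
regress_site_on_age <- function(samples, site_id) {
  if (!site_id %in% names(samples)) {
    stop("site '", site_id, "' not in sample table", call. = FALSE)
  }
  keep <- !is.na(samples[[site_id]]) & !is.na(samples$age)
  age <- samples$age[keep]
  meth <- samples[[site_id]][keep]
  if (length(age) < 3L) {
    stop("degenerate input: fewer than 3 samples with site '", site_id,
         "' measured", call. = FALSE)
  }
  if (stats::sd(age) == 0) {
    stop("degenerate input: age is constant; regression undefined",
         call. = FALSE)
  }
  fit <- stats::lm(meth ~ age)
  r <- if (stats::sd(meth) == 0) 0 else stats::cor(age, meth)
  out <- data.frame(site_id = site_id,
                    slope = unname(stats::coef(fit)[2]),
                    intercept = unname(stats::coef(fit)[1]),
                    pearson_r = r,
                    r_squared = r^2,
                    n = length(age),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_regression", "data.frame")
  out
}

#' Per-site age regressions for a whole panel
#'
#' @param samples Sample data frame.
#' @param site_ids Site columns to regress; default every panel-looking
#'   numeric column besides `age`.
#' @return Data frame with one `site_regression` row per site.
#' @export
regress_panel_on_age <- function(samples,
                                 site_ids = setdiff(
                                   names(samples)[vapply(samples, is.numeric,
                                                         logical(1))],
                                   "age")) {
  do.call(rbind, lapply(site_ids, function(s) {
    as.data.frame(regress_site_on_age(samples, s))
  }))
}
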