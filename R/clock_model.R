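#' Define an epigenetic clock model
#'
#' A clock is an affine (optionally polynomial) combination of per-site
#' percent-methylation values: predicted age = intercept +
#' sum(coefficient * methylation^power). Small pyrosequencing clocks publish
#' their coefficients in this form; this package never fits them.
#'
#' @param model_id Name, e.g. `"clock2"`, `"clock4"`.
#' @param intercept Intercept in years.
#' @param terms Data frame with columns `site_id`, `coefficient` and
#'   optionally `power` (positive integer, default 1).
#' @param valid_age_range Optional `c(lo, hi)` in years. Predictions outside
#'   it are flagged, never clipped: systematic drift outside the calibration
#'   range (e.g. old-age under-prediction) is a finding, not an artifact to
#'   suppress.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(model_id, intercept, terms, valid_age_range = NULL) {
  if (!is.character(model_id) || length(model_id) != 1L || !nzchar(model_id)) {
    stop("`model_id` must be a single non-empty string", call. = FALSE)
  }
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept)) {
    stop("model '", model_id, "': intercept must be a finite number",
         call. = FALSE)
  }
  if (!is.data.frame(terms) || nrow(terms) == 0L) {
    stop("model '", model_id, "': needs at least one term", call. = FALSE)
  }
  if (is.null(terms$power)) terms$power <- 1L
  terms <- terms[c("site_id", "coefficient", "power")]
  if (!is.numeric(terms$coefficient) || any(!is.finite(terms$coefficient))) {
    stop("model '", model_id, "': coefficients must be finite numbers",
         call. = FALSE)
  }
  if (any(terms$power != round(terms$power)) || any(terms$power < 1)) {
    stop("model '", model_id, "': powers must be positive integers",
         call. = FALSE)
  }
  key <- paste(terms$site_id, terms$power)
  if (anyDuplicated(key)) {
    stop("model '", model_id, "': duplicate (site_id, power) term",
         call. = FALSE)
  }
  if (!is.null(valid_age_range)) {
    if (length(valid_age_range) != 2L || !is.numeric(valid_age_range) ||
        valid_age_range[1] > valid_age_range[2]) {
      stop("model '", model_id, "': valid_age_range must be c(lo, hi)",
           call. = FALSE)
    }
  }
  structure(list(model_id = model_id, intercept = intercept, terms = terms,
                 valid_age_range = valid_age_range),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model>", x$model_id, "\n")
  cat("  predicted age =", format(x$intercept), "+",
      paste(sprintf("%s * m(%s)%s", format(x$terms$coefficient),
                    x$terms$site_id,
                    ifelse(x$terms$power == 1, "",
                           paste0("^", x$terms$power))),
            collapse = " + "), "\n")
  if (!is.null(x$valid_age_range)) {
    cat("  calibrated for ages", x$valid_age_range[1], "-",
        x$valid_age_range[2], "\n")
  }
  invisible(x)
}

#' Read clock models from a YAML config
#'
#' Expected layout:
#' ```yaml
#' models:
#'   - id: clock2
#'     intercept: 10.0
#'     terms:
#'       - {site: ELOVL2_6, coef: 0.5}
#'       - {site: ASPA_1, coef: -1.2, power: 1}
#'     valid_age_range: [0, 101]   # optional
#' ```
#'
#' @param path YAML file path.
#' @return A named list of [clock_model()] objects.
#' @export
read_clock_config <- function(path) {
  if (!file.exists(path)) stop("clock config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$models) || !length(cfg$models)) {
    stop("clock config format error: no `models` entry", call. = FALSE)
  }
  models <- lapply(cfg$models, function(m) {
    if (is.null(m$id)) {
      stop("clock config format error: model without `id`", call. = FALSE)
    }
    if (!is.numeric(m$intercept)) {
      stop("clock config format error: model '", m$id,
           "': intercept missing or non-numeric", call. = FALSE)
    }
    if (is.null(m$terms) || !length(m$terms)) {
      stop("model '", m$id, "': needs at least one term", call. = FALSE)
    }
    terms <- do.call(rbind, lapply(m$terms, function(tm) {
      if (is.null(tm$site) || is.null(tm$coef) || !is.numeric(tm$coef)) {
        stop("clock config format error: model '", m$id,
             "': each term needs `site` and numeric `coef`", call. = FALSE)
      }
      data.frame(site_id = tm$site, coefficient = as.numeric(tm$coef),
                 power = if (is.null(tm$power)) 1L else as.integer(tm$power),
                 stringsAsFactors = FALSE)
    }))
    clock_model(m$id, m$intercept, terms,
                valid_age_range = if (!is.null(m$valid_age_range))
                  as.numeric(m$valid_age_range))
  })
  ids <- vapply(models, `[[`, "", "model_id")
  if (anyDuplicated(ids)) {
    stop("clock config validation error: duplicate model id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(models) <- ids
  models
}

#' Write clock models to a YAML config
#'
#' @param models A `clock_model` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clock_config <- function(models, path) {
  if (inherits(models, "clock_model")) models <- list(models)
  cfg <- list(models = lapply(models, function(m) {
    out <- list(
      id = m$model_id,
      intercept = m$intercept,
      terms = lapply(seq_len(nrow(m$terms)), function(i) {
        list(site = m$terms$site_id[i], coef = m$terms$coefficient[i],
             power = as.integer(m$terms$power[i]))
      })
    )
    if (!is.null(m$valid_age_range)) out$valid_age_range <- m$valid_age_range
    out
  }))
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}
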