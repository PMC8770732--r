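#' Per-site generative model
#'
#' Methylation at one CpG drifts linearly with age with homoscedastic
#' Gaussian noise; beyond an optional knot age the drift slope is multiplied
#' by an attenuation factor, emulating the slowed methylation drift that
#' makes clocks under-predict in the oldest old:
#' `m = baseline + slope*min(age, knot) + factor*slope*max(0, age - knot)
#'  + N(0, noise_sd)`, clipped to \[0, 100\].
#'
#' @param site_id Site key.
#' @param baseline Percent methylation at age 0.
#' @param slope Percent methylation per year (sign gives the drift
#'   direction).
#' @param noise_sd Gaussian noise standard deviation, percent.
#' @param attenuation_knot Knot age in years, or `NULL` for no attenuation.
#' @param attenuation_factor Multiplier in \[0, 1\] applied to the slope
#'   beyond the knot (1 = no attenuation).
#' @return A list of class `site_model`.
#' @export
site_model <- function(site_id, baseline, slope, noise_sd,
                       attenuation_knot = NULL, attenuation_factor = 1) {
  stopifnot(is.character(site_id), length(site_id) == 1L)
  if (!is.numeric(baseline) || baseline < 0 || baseline > 100) {
    stop("site '", site_id, "': baseline must be a percent in [0, 100]",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("site '", site_id, "': noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.null(attenuation_knot) &&
      (!is.numeric(attenuation_knot) || attenuation_knot <= 0)) {
    stop("site '", site_id, "': attenuation_knot must be positive",
         call. = FALSE)
  }
  if (attenuation_factor < 0 || attenuation_factor > 1) {
    stop("site '", site_id, "': attenuation_factor must be in [0, 1]",
         call. = FALSE)
  }
  structure(list(site_id = site_id, baseline = baseline, slope = slope,
                 noise_sd = noise_sd, attenuation_knot = attenuation_knot,
                 attenuation_factor = attenuation_factor),
            class = "site_model")
}

# mean methylation trajectory of one site at given ages (no noise, no clip)
site_mean_trajectory <- function(site, age) {
  k <- site$attenuation_knot
  if (is.null(k)) {
    site$baseline + site$slope * age
  } else {
    site$baseline + site$slope * pmin(age, k) +
      site$attenuation_factor * site$slope * pmax(0, age - k)
  }
}

#' Reference cohort age/sex sampler
#'
#' Cell-weighted sampler over five age bands by sex, with the cell counts of
#' the reference 153-person cohort (ages 0--101, 96 women / 57 men; over a
#' third of it aged 81+). Each simulated individual draws a (band, sex) cell
#' with probability proportional to the cell count, then an age uniformly
#' within the band so completed years land in the band.
#'
#' @return An `age_sampler` list.
#' @export
table1_age_sampler <- function() {
  cells <- data.frame(
    lo = c(0, 21, 41, 61, 81),
    hi = c(20, 40, 60, 80, 101),
    female = c(13, 12, 12, 14, 45),
    male = c(11, 12, 13, 11, 10)
  )
  structure(list(type = "table", cells = cells), class = "age_sampler")
}

#' Uniform age sampler
#'
#' @param lo,hi Age range in years (continuous uniform).
#' @param female_share Probability a simulated individual is female.
#' @return An `age_sampler` list.
#' @export
uniform_age_sampler <- function(lo, hi, female_share = 0.5) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo <= hi,
            female_share >= 0, female_share <= 1)
  structure(list(type = "uniform", lo = lo, hi = hi,
                 female_share = female_share),
            class = "age_sampler")
}

#' Default calibrated site models
#'
#' Four-site panel whose age--methylation correlations over the reference
#' cohort's age distribution land at the magnitudes reported for these
#' markers (ELOVL2_6 r = 0.94, ASPA_1 r = -0.79, PDE4C_1 r = 0.92,
#' EDARADD_1 r = -0.90). The calibration is analytic, not tabulated: given a
#' target correlation r, slope b and the sampler's age standard deviation
#' `sd_age`, the noise must satisfy `noise_sd = |b| * sd_age *
#' sqrt(1/r^2 - 1)`. `sd_age` (about 30.7 y) is computed in closed form from
#' the band-weighted uniform mixture of [table1_age_sampler()]. Baselines
#' keep mean trajectories several noise SDs inside \[0, 100\] across ages
#' 0--101 so boundary clipping is negligible (< 0.1% of draws).
#'
#' @param attenuation_knot Optional knot age applied to every site.
#' @param attenuation_factor Slope multiplier beyond the knot.
#' @return Named list of [site_model()]s.
#' @export
default_site_models <- function(attenuation_knot = NULL,
                                attenuation_factor = 1) {
  sd_age <- table1_age_sd()
  spec <- list(
    ELOVL2_6  = list(baseline = 20, slope =  0.50, r =  0.94),
    ASPA_1    = list(baseline = 50, slope = -0.25, r = -0.79),
    PDE4C_1   = list(baseline = 20, slope =  0.35, r =  0.92),
    EDARADD_1 = list(baseline = 60, slope = -0.30, r = -0.90)
  )
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    site_model(nm, baseline = s$baseline, slope = s$slope,
               noise_sd = abs(s$slope) * sd_age * sqrt(1 / s$r^2 - 1),
               attenuation_knot = attenuation_knot,
               attenuation_factor = attenuation_factor)
  })
  names(out) <- names(spec)
  out
}

# SD of age under the table sampler: mixture of uniforms on [lo, hi + 1)
table1_age_sd <- function() {
  cells <- table1_age_sampler()$cells
  w <- (cells$female + cells$male) / sum(cells$female + cells$male)
  mu <- (cells$lo + cells$hi + 1) / 2
  v <- (cells$hi + 1 - cells$lo)^2 / 12
  m <- sum(w * mu)
  sqrt(sum(w * (v + mu^2)) - m^2)
}

#' Cohort generator configuration
#'
#' @param n Number of individuals.
#' @param seed Integer seed; every draw in [simulate_cohort()] derives from
#'   it, so identical configs give identical cohorts.
#' @param age_sampler [table1_age_sampler()] (default) or
#'   [uniform_age_sampler()].
#' @param sites Named list of [site_model()]s; default
#'   [default_site_models()].
#' @param sex_offset Percent methylation added at every site for individuals
#'   of `sex_offset_sex` (default 0: no sex effect).
#' @param sex_offset_sex Which sex receives the offset.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 153, seed = NULL,
                          age_sampler = table1_age_sampler(),
                          sites = default_site_models(),
                          sex_offset = 0,
                          sex_offset_sex = c("female", "male")) {
  sex_offset_sex <- match.arg(sex_offset_sex)
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!inherits(age_sampler, "age_sampler")) {
    stop("`age_sampler` must come from table1_age_sampler() or ",
         "uniform_age_sampler()", call. = FALSE)
  }
  if (!length(sites) || !all(vapply(sites, inherits, TRUE, "site_model"))) {
    stop("`sites` must be a non-empty list of site_model objects",
         call. = FALSE)
  }
  names(sites) <- vapply(sites, `[[`, "", "site_id")
  structure(list(n = as.integer(n), seed = seed, age_sampler = age_sampler,
                 sites = sites, sex_offset = sex_offset,
                 sex_offset_sex = sex_offset_sex),
            class = "cohort_config")
}

#' Simulate a cohort
#'
#' Draws ages and sexes from the configured sampler, then per-site percent
#' methylation from each [site_model()]. Reproducible: the same config and
#' seed give byte-identical cohorts; per-site noise streams are derived
#' deterministically from the seed so adding a site never perturbs the
#' others. Values falling outside \[0, 100\] are clipped and the clip counts
#' recorded in the `"clipping"` attribute.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Sample data frame (`sample_id`, `sex`, `age`, one column per
#'   site), with attributes `"clipping"` (per-site clip counts) and
#'   `"config"`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(seed)) {
    stop("validation error: a seed is required for reproducible simulation",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  n <- config$n
  smp <- config$age_sampler

  set.seed(seed)
  if (smp$type == "table") {
    cells <- smp$cells
    long <- rbind(
      data.frame(lo = cells$lo, hi = cells$hi, sex = "female",
                 count = cells$female),
      data.frame(lo = cells$lo, hi = cells$hi, sex = "male",
                 count = cells$male)
    )
    idx <- sample.int(nrow(long), n, replace = TRUE,
                      prob = long$count / sum(long$count))
    # uniform on [lo, hi + 1) so floor(age) is inside the inclusive band
    age <- stats::runif(n, long$lo[idx], long$hi[idx] + 1)
    sex <- long$sex[idx]
  } else {
    age <- stats::runif(n, smp$lo, smp$hi)
    sex <- ifelse(stats::runif(n) < smp$female_share, "female", "male")
  }

  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)),
                    sex = sex, age = age, stringsAsFactors = FALSE)
  clipping <- data.frame(site_id = character(0), n_clipped = integer(0))
  for (i in seq_along(config$sites)) {
    site <- config$sites[[i]]
    # deterministic per-site substream: site order fixes the stream
    set.seed((seed + 104729L * i) %% .Machine$integer.max)
    m <- site_mean_trajectory(site, age) +
      stats::rnorm(n, 0, site$noise_sd)
    if (config$sex_offset != 0) {
      m <- m + ifelse(sex == config$sex_offset_sex, config$sex_offset, 0)
    }
    n_clip <- sum(m < 0 | m > 100)
    clipping <- rbind(clipping,
                      data.frame(site_id = site$site_id, n_clipped = n_clip))
    out[[site$site_id]] <- pmin(100, pmax(0, m))
  }
  attr(out, "clipping") <- clipping
  attr(out, "config") <- config
  out
}

#' Clock matched to a generator
#'
#' The exact inverse of the noiseless generator below any attenuation knot:
#' for one site, predicted age = (m - baseline) / slope; for several sites,
#' the equal-weight average of the single-site inversions. With zero noise
#' and no attenuation it recovers age exactly, which makes it the reference
#' clock for pipeline self-tests and noise-law checks.
#'
#' @param config A [cohort_config()].
#' @param site_ids Subset of site ids to invert; default all sites.
#' @param model_id Model name; default `"matched<k>"`.
#' @return A [clock_model()]. Errors if any selected slope is zero or the
#'   selected sites disagree on the attenuation knot.
#' @export
matched_clock <- function(config, site_ids = names(config$sites),
                          model_id = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  sites <- config$sites[site_ids]
  if (any(vapply(sites, is.null, TRUE))) {
    stop("unknown site id(s): ",
         paste(setdiff(site_ids, names(config$sites)), collapse = ", "),
         call. = FALSE)
  }
  slopes <- vapply(sites, `[[`, 0, "slope")
  if (any(slopes == 0)) {
    stop("validation error: zero slope at ",
         paste(names(slopes)[slopes == 0], collapse = ", "),
         "; a flat site cannot be inverted", call. = FALSE)
  }
  knots <- lapply(sites, `[[`, "attenuation_knot")
  has_knot <- !vapply(knots, is.null, TRUE)
  if (any(has_knot) &&
      (!all(has_knot) || length(unique(unlist(knots))) > 1)) {
    stop("selected sites must share one attenuation knot (or none)",
         call. = FALSE)
  }
  k <- length(sites)
  baselines <- vapply(sites, `[[`, 0, "baseline")
  clock_model(
    model_id = if (is.null(model_id)) paste0("matched", k) else model_id,
    intercept = mean(-baselines / slopes),
    terms = data.frame(site_id = names(sites),
                       coefficient = (1 / slopes) / k,
                       power = 1L,
                       stringsAsFactors = FALSE),
    valid_age_range = if (any(has_knot)) c(0, unlist(knots)[1]) else NULL
  )
}
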