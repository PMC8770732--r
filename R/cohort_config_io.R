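#' Read a cohort generator configuration from YAML
#'
#' Layout (every key optional; omitted keys fall back to the calibrated
#' defaults):
#' ```yaml
#' n: 153
#' age_sampler: {type: table}            # or {type: uniform, lo: 18, hi: 80}
#' sex_offset: 0
#' attenuation: {knot: 80, factor: 0.3}  # applied to default sites
#' sites:                                # overrides default sites entirely
#'   - {site: ELOVL2_6, baseline: 20, slope: 0.5, noise_sd: 5.6}
#' ```
#'
#' @param path YAML file path.
#' @param seed Optional seed stored in the config.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("cohort config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)

  knot <- cfg$attenuation$knot
  factor_ <- if (is.null(cfg$attenuation$factor)) 1 else cfg$attenuation$factor
  sites <- if (is.null(cfg$sites)) {
    default_site_models(attenuation_knot = knot,
                        attenuation_factor = factor_)
  } else {
    lapply(cfg$sites, function(s) {
      if (is.null(s$site) || is.null(s$baseline) || is.null(s$slope) ||
          is.null(s$noise_sd)) {
        stop("cohort config format error: each site needs ",
             "`site`, `baseline`, `slope`, `noise_sd`", call. = FALSE)
      }
      site_model(s$site, s$baseline, s$slope, s$noise_sd,
                 attenuation_knot = if (!is.null(s$attenuation_knot))
                   s$attenuation_knot else knot,
                 attenuation_factor = if (!is.null(s$attenuation_factor))
                   s$attenuation_factor else factor_)
    })
  }

  sampler <- if (is.null(cfg$age_sampler) ||
                 identical(cfg$age_sampler$type, "table")) {
    table1_age_sampler()
  } else if (identical(cfg$age_sampler$type, "uniform")) {
    uniform_age_sampler(cfg$age_sampler$lo, cfg$age_sampler$hi,
                        female_share = if (is.null(cfg$age_sampler$female_share))
                          0.5 else cfg$age_sampler$female_share)
  } else {
    stop("cohort config format error: unknown age_sampler type '",
         cfg$age_sampler$type, "'", call. = FALSE)
  }

  cohort_config(
    n = if (is.null(cfg$n)) 153 else cfg$n,
    seed = if (is.null(seed)) cfg$seed else seed,
    age_sampler = sampler,
    sites = sites,
    sex_offset = if (is.null(cfg$sex_offset)) 0 else cfg$sex_offset,
    sex_offset_sex = if (is.null(cfg$sex_offset_sex)) "female"
                     else cfg$sex_offset_sex
  )
}
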