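#' Default generator and pipeline configuration
#'
#' A nested list of every tunable in the pipeline. Generator ranges span the
#' magnitudes observed across Indian states (per-capita GDP roughly $600 to
#' $5500, ambient PM2.5 from the mid-teens to above 200 ug/m3, solid-fuel
#' use from a few percent to above 80%, ozone 47-77 ppb); between-state
#' spread is drawn log-uniformly for strictly positive quantities.
#' Serialized as JSON by [write_config()] / [read_config()].
#'
#' @return A validated config list.
#' @export
default_config <- function() {
  validate_config(list(
    n_states = 31L,
    exposure_cv = 0.25,          # CV of the within-state exposure distribution
    discount_rate = 0.06,
    sensitivity_rates = c(0.04, 0.08),
    nonmarket_share = 0.30,
    min_working_age = 15L,
    horizon_age = 65L,
    growth_rate = 0.05,          # historical real growth of output per worker
    n_draws = 100L,
    draw_cv_exposure = 0.10,
    draw_cv_envelope = 0.10,
    ranges = list(
      population_total = c(3e5, 2.3e8),       # log-uniform, persons
      gdp_per_capita_usd = c(600, 5500),      # log-uniform
      labour_share = c(0.40, 0.60),           # uniform
      target_l65_over_l0 = c(0.60, 0.85),     # uniform
      pm25_mean = c(16, 218),                 # log-uniform, ug/m3
      solid_fuel_prop = c(0.05, 0.85),        # uniform
      ozone_ppb = c(47, 77)                   # uniform
    )
  ))
}

#' Validate a configuration list
#'
#' @param config a config list (see [default_config()]).
#' @return `config` (with integer fields coerced) or a configuration error
#'   naming the offending field.
#' @export
validate_config <- function(config) {
  need <- c("n_states", "exposure_cv", "discount_rate", "sensitivity_rates",
            "nonmarket_share", "min_working_age", "horizon_age",
            "growth_rate", "n_draws", "draw_cv_exposure", "draw_cv_envelope",
            "ranges")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop_config(sprintf("config missing field '%s'", missing[1L]))
  }
  if (!is_scalar_number(config$n_states) || config$n_states < 1) {
    stop_config("n_states must be a positive integer")
  }
  config$n_states <- as.integer(config$n_states)
  config$n_draws <- as.integer(config$n_draws)
  rates <- c(config$discount_rate, config$sensitivity_rates)
  if (any(rates <= 0 | rates >= 1)) {
    stop_config("discount and sensitivity rates must lie in (0, 1)")
  }
  if (config$min_working_age >= config$horizon_age) {
    stop_config("min_working_age must be below horizon_age")
  }
  rng_need <- c("population_total", "gdp_per_capita_usd", "labour_share",
                "target_l65_over_l0", "pm25_mean", "solid_fuel_prop",
                "ozone_ppb")
  rmiss <- setdiff(rng_need, names(config$ranges))
  if (length(rmiss)) {
    stop_config(sprintf("config ranges missing '%s'", rmiss[1L]))
  }
  for (nm in rng_need) {
    r <- config$ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L] || r[1L] <= 0) {
      stop_config(sprintf("malformed range '%s' (need 0 < lo <= hi)", nm))
    }
  }
  config
}

#' Read / write configuration as JSON
#'
#' @param path file path.
#' @return [read_config()] returns a validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("config file not found: %s", path))
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(config)
}

#' @rdname read_config
#' @param config a config list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(validate_config(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
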