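#' Age-specific employment-to-population profile
#'
#' The fraction of people in each age group who are working, used both to
#' weight output per worker down to expected output per person and (times
#' population) to reconcile the employed count in the economy parameters.
#'
#' @param e numeric vector of working fractions, one per age group.
#' @param grid an [age_grid()].
#' @return Object of class `employment_profile`.
#' @export
employment_profile <- function(e, grid = age_grid()) {
  if (length(e) != grid$n) stop_validation("employment profile length must match age grid")
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1)) {
    stop_validation("employment fractions must lie in [0, 1]")
  }
  structure(list(e = as.numeric(e), grid = grid), class = "employment_profile")
}

# Working fraction at a single age.
employment_at_age <- function(employment, age) {
  employment$e[age_to_group(employment$grid, age)]
}

#' Economy parameters for one state
#'
#' The macro inputs of the output-based cost-of-illness model. Output per
#' worker at baseline is `labour_share * gdp / employed_count`; it grows at
#' `growth_rate` from the year after baseline and future losses are
#' discounted at `discount_rate` (default 6%, the 10-year government bond
#' yield convention). People of working age who are not employed are
#' credited `nonmarket_share` (default 30%) of market output for home
#' production. Lost output accrues from `min_working_age` (default 15) up to
#' but excluding `horizon_age` (default 65, the assumed retirement age).
#'
#' @param gdp state GDP, US$ millions per year.
#' @param labour_share labour share of GDP, in (0, 1).
#' @param employed_count number of employed persons.
#' @param growth_rate annual real growth of output per worker (fraction).
#' @param discount_rate annual discount rate (fraction), default 0.06.
#' @param nonmarket_share non-market output as a share of market output for
#'   working-age non-workers, default 0.30.
#' @param min_working_age first working age in years, default 15.
#' @param horizon_age retirement horizon in years (exclusive), default 65.
#' @return Object of class `economy_params`.
#' @export
economy_params <- function(gdp, labour_share, employed_count, growth_rate,
                           discount_rate = 0.06, nonmarket_share = 0.30,
                           min_working_age = 15L, horizon_age = 65L) {
  if (!is_scalar_number(gdp) || gdp <= 0) stop_validation("gdp must be positive")
  if (!is_scalar_number(labour_share) || labour_share <= 0 || labour_share >= 1) {
    stop_validation("labour_share must lie strictly inside (0, 1)")
  }
  if (!is_scalar_number(employed_count) || employed_count <= 0) {
    stop_validation("employed_count must be positive")
  }
  if (!is_scalar_number(nonmarket_share) || nonmarket_share < 0 || nonmarket_share > 1) {
    stop_validation("nonmarket_share must lie in [0, 1]")
  }
  if (min_working_age >= horizon_age) {
    stop_validation("min_working_age must be below horizon_age")
  }
  structure(
    list(gdp = gdp, labour_share = labour_share,
         employed_count = employed_count, growth_rate = growth_rate,
         discount_rate = discount_rate, nonmarket_share = nonmarket_share,
         min_working_age = as.integer(min_working_age),
         horizon_age = as.integer(horizon_age)),
    class = "economy_params"
  )
}

#' Exposure summary for one state
#'
#' @param pm25_mean population-weighted annual mean ambient PM2.5, ug/m3.
#' @param solid_fuel_prop proportion of the population cooking with solid
#'   fuels (household air pollution exposure), in \[0, 1\].
#' @param ozone_ppb seasonal 8-h daily maximum ozone, parts per billion.
#' @return Object of class `exposure_summary`.
#' @export
exposure_summary <- function(pm25_mean, solid_fuel_prop, ozone_ppb) {
  if (pm25_mean < 0 || ozone_ppb < 0) stop_validation("exposures must be non-negative")
  if (solid_fuel_prop < 0 || solid_fuel_prop > 1) {
    stop_validation("solid_fuel_prop must lie in [0, 1]")
  }
  structure(
    list(pm25_mean = pm25_mean, solid_fuel_prop = solid_fuel_prop,
         ozone_ppb = ozone_ppb),
    class = "exposure_summary"
  )
}

#' Complete input bundle for one geographic unit
#'
#' @param state_id character label.
#' @param population persons per age group (vector matching the grid).
#' @param life_table a [life_table()].
#' @param employment an [employment_profile()].
#' @param economy an [economy_params()].
#' @param exposure an [exposure_summary()].
#' @param cause_envelopes data.frame with columns `age_group`, `cause`,
#'   `deaths`, `yll`, `yld`: all-risk totals per age group and cause.
#' @param grid an [age_grid()].
#' @return Object of class `state_panel`, validated.
#' @export
state_panel <- function(state_id, population, life_table, employment,
                        economy, exposure, cause_envelopes,
                        grid = age_grid()) {
  panel <- structure(
    list(state_id = as.character(state_id), population = as.numeric(population),
         life_table = life_table, employment = employment, economy = economy,
         exposure = exposure, cause_envelopes = cause_envelopes, grid = grid),
    class = "state_panel"
  )
  validate_panel(panel)
  panel
}

#' Validate every structural invariant of a state panel
#'
#' Checks population non-negativity, envelope consistency (deaths in an age
#' group cannot exceed its population; YLL/YLD non-negative), employment
#' zero below the minimum working age, and component types. Called by
#' [state_panel()] and by the CSV reader, so invariant breaches are caught
#' at load, with the state and field named.
#'
#' @param panel a `state_panel`.
#' @return `panel`, invisibly, or a validation error.
#' @export
validate_panel <- function(panel) {
  id <- panel$state_id
  grid <- panel$grid
  if (length(panel$population) != grid$n) {
    stop_validation(sprintf("%s: population length does not match age grid", id))
  }
  if (any(!is.finite(panel$population)) || any(panel$population < 0)) {
    stop_validation(sprintf("%s: population must be non-negative", id))
  }
  if (!inherits(panel$life_table, "life_table")) {
    stop_validation(sprintf("%s: life_table is not a life_table", id))
  }
  if (!inherits(panel$employment, "employment_profile")) {
    stop_validation(sprintf("%s: employment is not an employment_profile", id))
  }
  if (!inherits(panel$economy, "economy_params")) {
    stop_validation(sprintf("%s: economy is not economy_params", id))
  }
  if (!inherits(panel$exposure, "exposure_summary")) {
    stop_validation(sprintf("%s: exposure is not an exposure_summary", id))
  }
  below <- grid$starts + ifelse(is.na(grid$width), 0L, grid$width) <=
    panel$economy$min_working_age
  if (any(panel$employment$e[below] > 0)) {
    stop_validation(sprintf("%s: employment positive below min_working_age", id))
  }
  env <- panel$cause_envelopes
  need <- c("age_group", "cause", "deaths", "yll", "yld")
  missing <- setdiff(need, names(env))
  if (length(missing)) {
    stop_validation(sprintf("%s: cause_envelopes missing column '%s'",
                            id, missing[1L]))
  }
  if (any(!env$age_group %in% grid$labels)) {
    stop_validation(sprintf("%s: cause_envelopes has age groups off the grid", id))
  }
  if (any(env$deaths < 0) || any(env$yll < 0) || any(env$yld < 0)) {
    stop_validation(sprintf("%s: envelope measures must be non-negative", id))
  }
  deaths_by_age <- tapply(env$deaths, env$age_group, sum)
  pop <- stats::setNames(panel$population, grid$labels)
  over <- deaths_by_age > pop[names(deaths_by_age)] + 1e-9
  if (any(over)) {
    stop_validation(sprintf("%s: envelope deaths exceed population in age group %s",
                            id, names(deaths_by_age)[over][1L]))
  }
  invisible(panel)
}

#' @export
print.state_panel <- function(x, ...) {
  cat("<state_panel> ", x$state_id,
      ": pop ", format(round(sum(x$population)), big.mark = ","),
      ", GDP ", format(round(x$economy$gdp), big.mark = ","), " M$",
      ", PM2.5 ", signif(x$exposure$pm25_mean, 3), " ug/m3\n", sep = "")
  invisible(x)
}
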