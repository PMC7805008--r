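# CSV readers/writers for every table schema. Dialect is fixed: UTF-8,
# comma separator, '.' decimal, mandatory header row. Readers validate the
# header against the schema (schema error naming the missing column) and then
# enforce the type invariants (validation error naming state and field);
# there is no silent coercion.

check_columns <- function(df, need, what, path) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_schema(sprintf("%s (%s): missing column '%s'", what, path, missing[1L]))
  }
  invisible(df)
}

read_table_checked <- function(path, need, what) {
  if (!file.exists(path)) stop_schema(sprintf("%s: file not found: %s", what, path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_schema(sprintf("%s (%s): unreadable CSV: %s",
                                            what, path, conditionMessage(e)))
  )
  check_columns(df, need, what, path)
  df
}

panel_paths <- function(dir) {
  files <- c(population = "population.csv", life_table = "life_table.csv",
             employment = "employment.csv", economy = "economy.csv",
             exposure = "exposure.csv", cause_envelopes = "cause_envelopes.csv")
  stats::setNames(file.path(dir, files), names(files))
}

#' Write a panel collection to a directory of CSV files
#'
#' One CSV per table: `population.csv` (state_id, age_group, population),
#' `life_table.csv` (state_id, age, l — single years), `employment.csv`
#' (state_id, age_group, employed_fraction), `economy.csv` (one row per
#' state), `exposure.csv` (state_id, pm25_mean, solid_fuel_prop, ozone_ppb)
#' and `cause_envelopes.csv` (state_id, age_group, cause, deaths, yll, yld).
#'
#' @param panels named list of [state_panel()]s.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- panel_paths(dir)
  grab <- function(f) do.call(rbind, lapply(panels, f))
  wr <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(grab(function(x) data.frame(
    state_id = x$state_id, age_group = x$grid$labels,
    population = x$population, stringsAsFactors = FALSE)), p[["population"]])
  wr(grab(function(x) data.frame(
    state_id = x$state_id, age = x$life_table$ages, l = x$life_table$l,
    stringsAsFactors = FALSE)), p[["life_table"]])
  wr(grab(function(x) data.frame(
    state_id = x$state_id, age_group = x$grid$labels,
    employed_fraction = x$employment$e, stringsAsFactors = FALSE)),
    p[["employment"]])
  wr(grab(function(x) {
    ec <- x$economy
    data.frame(state_id = x$state_id, gdp = ec$gdp,
               labour_share = ec$labour_share,
               employed_count = ec$employed_count,
               growth_rate = ec$growth_rate, discount_rate = ec$discount_rate,
               nonmarket_share = ec$nonmarket_share,
               min_working_age = ec$min_working_age,
               horizon_age = ec$horizon_age, stringsAsFactors = FALSE)
  }), p[["economy"]])
  wr(grab(function(x) data.frame(
    state_id = x$state_id, pm25_mean = x$exposure$pm25_mean,
    solid_fuel_prop = x$exposure$solid_fuel_prop,
    ozone_ppb = x$exposure$ozone_ppb, stringsAsFactors = FALSE)),
    p[["exposure"]])
  wr(grab(function(x) cbind(state_id = x$state_id, x$cause_envelopes)),
     p[["cause_envelopes"]])
  invisible(dir)
}

#' Read a panel collection from a directory of CSV files
#'
#' Inverse of [write_panel()]. Every type invariant is enforced at load:
#' malformed headers raise schema errors naming the column; invariant
#' breaches raise validation errors naming the state and field.
#'
#' @param dir directory holding the six panel CSVs.
#' @return Named list of [state_panel()]s.
#' @export
read_panel <- function(dir) {
  p <- panel_paths(dir)
  pop <- read_table_checked(p[["population"]],
                            c("state_id", "age_group", "population"), "population")
  ltab <- read_table_checked(p[["life_table"]], c("state_id", "age", "l"),
                             "life_table")
  emp <- read_table_checked(p[["employment"]],
                            c("state_id", "age_group", "employed_fraction"),
                            "employment")
  eco <- read_table_checked(p[["economy"]],
                            c("state_id", "gdp", "labour_share", "employed_count",
                              "growth_rate", "discount_rate", "nonmarket_share",
                              "min_working_age", "horizon_age"), "economy")
  exp_ <- read_table_checked(p[["exposure"]],
                             c("state_id", "pm25_mean", "solid_fuel_prop",
                               "ozone_ppb"), "exposure")
  env <- read_table_checked(p[["cause_envelopes"]],
                            c("state_id", "age_group", "cause", "deaths",
                              "yll", "yld"), "cause_envelopes")
  grid <- age_grid()
  ids <- unique(pop$state_id)
  if (!length(ids)) stop_schema("population table has no rows")
  panels <- lapply(ids, function(id) {
    pp <- pop[pop$state_id == id, ]
    pp <- pp[match(grid$labels, pp$age_group), ]
    if (any(is.na(pp$population))) {
      stop_validation(sprintf("%s: population table misses age groups", id))
    }
    lrows <- ltab[ltab$state_id == id, ]
    lrows <- lrows[order(lrows$age), ]
    erows <- emp[emp$state_id == id, ]
    erows <- erows[match(grid$labels, erows$age_group), ]
    if (any(is.na(erows$employed_fraction))) {
      stop_validation(sprintf("%s: employment table misses age groups", id))
    }
    if (any(erows$employed_fraction < 0 | erows$employed_fraction > 1)) {
      stop_validation(sprintf("%s: employed_fraction outside [0, 1]", id))
    }
    ec <- eco[eco$state_id == id, ]
    if (nrow(ec) != 1L) {
      stop_validation(sprintf("%s: economy table needs exactly one row", id))
    }
    state_panel(
      id, pp$population,
      life_table(lrows$l, grid),
      employment_profile(erows$employed_fraction, grid),
      economy_params(ec$gdp, ec$labour_share, ec$employed_count, ec$growth_rate,
                     ec$discount_rate, ec$nonmarket_share, ec$min_working_age,
                     ec$horizon_age),
      exposure_summary(exp_$pm25_mean[exp_$state_id == id][1L],
                       exp_$solid_fuel_prop[exp_$state_id == id][1L],
                       exp_$ozone_ppb[exp_$state_id == id][1L]),
      env[env$state_id == id, c("age_group", "cause", "deaths", "yll", "yld")],
      grid
    )
  })
  stats::setNames(panels, ids)
}

#' Read and write attributable-burden tables
#'
#' Burden CSV columns: `state_id`, `age_group`, `cause`, `risk`, `deaths`,
#' `yll`, `yld`, `daly`. On read, negativity and the DALY = YLL + YLD
#' identity (1e-9 relative) are enforced.
#'
#' @param path CSV path.
#' @return [read_burden()] returns the validated burden data.frame.
#' @export
read_burden <- function(path) {
  df <- read_table_checked(path, c("state_id", "age_group", "cause", "risk",
                                   "deaths", "yll", "yld", "daly"), "burden")
  if (any(df$deaths < 0 | df$yll < 0 | df$yld < 0 | df$daly < 0)) {
    stop_validation("burden: measures must be non-negative")
  }
  bad <- abs(df$daly - (df$yll + df$yld)) > 1e-9 * pmax(df$daly, 1)
  if (any(bad)) {
    stop_validation(sprintf("burden: DALY != YLL + YLD for state %s",
                            df$state_id[bad][1L]))
  }
  df
}

#' @rdname read_burden
#' @param burden a burden data.frame.
#' @export
write_burden <- function(burden, path) {
  utils::write.csv(burden, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write loss-result tables
#'
#' Loss CSV columns mirror the state-level reporting layout (mortality,
#' morbidity and total US$ millions, percent of GDP, per-capita US$) plus a
#' `risk` column and the `gdp`/`population` denominators.
#'
#' @param path CSV path.
#' @return [read_losses()] returns the loss data.frame.
#' @export
read_losses <- function(path) {
  df <- read_table_checked(path, c("state_id", "risk", "mortality_loss",
                                   "morbidity_loss", "total_loss", "pct_gdp",
                                   "per_capita", "gdp", "population"), "losses")
  class(df) <- c("loss_result", "data.frame")
  df
}

#' @rdname read_losses
#' @param losses a loss data.frame.
#' @export
write_losses <- function(losses, path) {
  utils::write.csv(losses, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read risk curves from CSV
#'
#' Expected columns: `risk`, `cause`, `kind` (`continuous`/`categorical`),
#' `exposure`, `rr`, `tmrel`. Continuous curves have one row per knot
#' (shared `tmrel`); categorical curves have a single row whose `rr` is the
#' exposed-category relative risk.
#'
#' @param path CSV path.
#' @return Named list of risk curves (names `"risk:cause"`).
#' @export
read_risk_curves <- function(path) {
  df <- read_table_checked(path, c("risk", "cause", "kind", "exposure", "rr",
                                   "tmrel"), "risk_curves")
  keys <- unique(df[, c("risk", "cause")])
  curves <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$risk == keys$risk[i] & df$cause == keys$cause[i], ]
    kind <- unique(sub$kind)
    if (length(kind) != 1L) {
      stop_schema(sprintf("risk_curves: mixed kinds for %s/%s",
                          keys$risk[i], keys$cause[i]))
    }
    if (kind == "categorical") {
      risk_curve_categorical(sub$rr[1L], risk = keys$risk[i],
                             cause = keys$cause[i])
    } else {
      sub <- sub[order(sub$exposure), ]
      risk_curve_continuous(sub$exposure, sub$rr, tmrel = sub$tmrel[1L],
                            risk = keys$risk[i], cause = keys$cause[i])
    }
  })
  stats::setNames(curves, paste(keys$risk, keys$cause, sep = ":"))
}

#' Read standard-population weights
#'
#' Columns `age_group`, `weight`; weights are normalised to sum to 1. The
#' packaged default approximates the WHO World Standard on the 5-year grid.
#'
#' @param path CSV path; defaults to the packaged standard.
#' @return Named numeric vector of weights by age-group label.
#' @export
read_standard_population <- function(path = system.file(
  "extdata", "standard_population.csv", package = "airburden")) {
  df <- read_table_checked(path, c("age_group", "weight"), "standard_population")
  if (any(df$weight < 0)) stop_validation("standard weights must be non-negative")
  stats::setNames(df$weight / sum(df$weight), df$age_group)
}
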