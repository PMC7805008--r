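# Internal-consistency checks against published headline values. The
# constants live in inst/extdata/published_values.csv (scalar values) and
# published_table2.csv (the state-level loss table); every check recomputes a
# published quantity from other published quantities at run time and compares
# at the printed precision using half-up rounding.

published_values <- function() {
  path <- system.file("extdata", "published_values.csv", package = "airburden")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$value, df$key)
}

published_state_table <- function() {
  path <- system.file("extdata", "published_table2.csv", package = "airburden")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Recompute published arithmetic identities
#'
#' Runs every internal-consistency check: shares of total deaths/DALYs,
#' the mortality + morbidity loss sum, percent-of-GDP and per-capita
#' derivations (against constants implied by the published pairs, computed
#' at run time, never hard-coded), between-state extremes ratios, the
#' lung-disease cause grouping, the health-care cost cross-multiplication,
#' the squared correlation coefficient, and the state-column sums of the
#' loss table against the national row (within a half-unit-per-state
#' rounding band).
#'
#' @return data.frame of class `verification_report` with columns
#'   `check_id`, `computed`, `printed`, `digits`, `tol` and `pass`. A check
#'   passes when the computed value, rounded half-up to the printed number
#'   of decimals, equals the printed value (or, for band checks, differs by
#'   at most `tol` before rounding).
#' @export
verify_paper_arithmetic <- function() {
  v <- published_values()
  t2 <- published_state_table()
  n_states <- nrow(t2)

  checks <- list(
    list("deaths_share_air_pct",
         share_of_total(v[["deaths_air_millions"]], v[["total_deaths_millions"]]),
         v[["printed_deaths_share_air_pct"]], 1),
    list("deaths_share_ambient_pm_pct",
         share_of_total(v[["deaths_ambient_pm_millions"]], v[["total_deaths_millions"]]),
         v[["printed_deaths_share_ambient_pm_pct"]], 1),
    list("deaths_share_household_pct",
         share_of_total(v[["deaths_household_millions"]], v[["total_deaths_millions"]]),
         v[["printed_deaths_share_household_pct"]], 1),
    list("deaths_share_ozone_pct",
         share_of_total(v[["deaths_ozone_millions"]], v[["total_deaths_millions"]]),
         v[["printed_deaths_share_ozone_pct"]], 1),
    list("daly_share_household_pct",
         share_of_total(v[["daly_household_millions"]], v[["total_daly_millions"]]),
         v[["printed_daly_share_household_pct"]], 1),
    list("total_loss_sum_musd",
         v[["mortality_loss_musd"]] + v[["morbidity_loss_musd"]],
         v[["total_loss_musd"]], 0),
    list("healthcare_cost_air_busd",
         v[["healthcare_total_busd"]] * v[["daly_share_air_fraction"]],
         v[["printed_healthcare_air_busd"]], 1),
    list("pm25_extremes_ratio",
         extremes_ratio(c(v[["pm25_state_min"]], v[["pm25_state_max"]])),
         v[["printed_pm25_extremes_ratio"]], 1),
    list("pct_gdp_extremes_ratio",
         extremes_ratio(c(v[["pct_gdp_state_min"]], v[["pct_gdp_state_max"]])),
         v[["printed_pct_gdp_extremes_ratio"]], 1),
    list("per_capita_extremes_ratio",
         extremes_ratio(c(v[["per_capita_state_min"]], v[["per_capita_state_max"]])),
         v[["printed_per_capita_extremes_ratio"]], 1),
    list("lung_group_daly_share_pct",
         cause_decomposition(
           c(copd = v[["daly_share_copd_pct"]],
             lri = v[["daly_share_lri_pct"]],
             lung_cancer = v[["daly_share_lung_cancer_pct"]],
             other = 100 - v[["daly_share_copd_pct"]] -
               v[["daly_share_lri_pct"]] - v[["daly_share_lung_cancer_pct"]]),
           groups = list(lung = c("copd", "lri", "lung_cancer"))
         )$groups[["lung"]],
         v[["printed_lung_group_daly_share_pct"]], 1),
    list("correlation_r2_household",
         v[["correlation_r_household"]]^2,
         v[["printed_correlation_r2_household"]], 2),
    # implied constants computed from published pairs at run time
    list("pct_gdp_national",
         pct_of_gdp(v[["total_loss_musd"]],
                    v[["total_loss_musd"]] / v[["pct_gdp_total"]] * 100),
         v[["pct_gdp_total"]], 2),
    list("per_capita_national_usd",
         per_capita(v[["total_loss_musd"]],
                    v[["total_loss_musd"]] * 1e6 / v[["per_capita_usd"]]),
         v[["per_capita_usd"]], 1),
    # state columns vs national row, within half a printed unit per state
    list("table2_mortality_sum_musd", sum(t2$premature_deaths_musd),
         v[["mortality_loss_musd"]], 0, 0.5 * n_states),
    list("table2_morbidity_sum_musd", sum(t2$morbidity_musd),
         v[["morbidity_loss_musd"]], 0, 0.5 * n_states),
    list("table2_total_sum_musd", sum(t2$total_musd),
         v[["total_loss_musd"]], 0, 0.5 * n_states)
  )

  rows <- lapply(checks, function(ck) {
    tol <- if (length(ck) >= 5L) ck[[5L]] else NA_real_
    computed <- as.numeric(ck[[2L]])
    printed <- as.numeric(ck[[3L]])
    digits <- ck[[4L]]
    pass <- if (is.na(tol)) {
      round_half_up(computed, digits) == printed
    } else {
      abs(computed - printed) <= tol
    }
    data.frame(check_id = ck[[1L]], computed = computed, printed = printed,
               digits = digits, tol = tol, pass = pass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("verification_report", "data.frame")
  out
}
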