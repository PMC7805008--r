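#' Population attributable fraction for a continuous exposure
#'
#' The comparative-risk-assessment PAF: with population mean relative risk
#' \eqn{\bar R = \sum_i w_i RR(x_i)} over a discrete exposure distribution,
#' \deqn{PAF = (\bar R - 1) / \bar R.}
#' It is the proportion of the cause's burden that would be removed if the
#' whole population were at the TMREL.
#'
#' @param curve a continuous [risk_curve_continuous()].
#' @param exposure exposure values of the discrete distribution.
#' @param weights non-negative weights summing to 1 (within 1e-9).
#' @return PAF in \[0, 1).
#' @export
paf_continuous <- function(curve, exposure, weights) {
  if (length(exposure) != length(weights)) {
    stop_validation("exposure and weights must have equal length")
  }
  if (any(weights < 0)) stop_validation("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop_validation("weights must sum to 1 (within 1e-9)")
  }
  rbar <- sum(weights * relative_risk(curve, exposure))
  (rbar - 1) / rbar
}

#' Population attributable fraction for a categorical exposure
#'
#' Two-category (exposed/unexposed) PAF:
#' \deqn{PAF = p (RR - 1) / (1 + p (RR - 1))}
#' with `p` the exposed proportion. Equals [paf_continuous()] with a point
#' mass at the exposed RR when `p = 1`.
#'
#' @param p_exposed exposed proportion, in \[0, 1\].
#' @param rr relative risk in the exposed category, >= 1.
#' @return PAF in \[0, 1).
#' @export
paf_categorical <- function(p_exposed, rr) {
  if (p_exposed < 0 || p_exposed > 1) stop_domain("p_exposed must lie in [0, 1]")
  if (rr < 1) stop_domain("protective exposures (rr < 1) are out of scope")
  excess <- p_exposed * (rr - 1)
  excess / (1 + excess)
}

#' Discretize a lognormal exposure distribution around a summary mean
#'
#' State exposure arrives as a single population-weighted mean; the PAF
#' integral needs a distribution. This helper spreads the mean over a fixed
#' multiplicative grid as a lognormal with coefficient of variation `cv`
#' (arithmetic mean preserved), with trapezoidal density weights normalised
#' to 1. `cv = 0` returns a point mass at the mean. The same discretization
#' is used by the synthetic generator and the burden stage, so burden
#' inversion is exact.
#'
#' @param mean arithmetic mean exposure (> 0 unless a point mass at 0).
#' @param cv coefficient of variation (default 0.25).
#' @param n_grid number of grid points (default 41).
#' @param span half-width of the grid in units of sdlog (default 3).
#' @return list with `exposure` and `weights`.
#' @export
exposure_distribution <- function(mean, cv = 0.25, n_grid = 41L, span = 3) {
  if (mean < 0) stop_domain("mean exposure must be non-negative")
  if (cv < 0) stop_domain("cv must be non-negative")
  if (cv == 0 || mean == 0) {
    return(list(exposure = mean, weights = 1))
  }
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- exp(meanlog + seq(-span, span, length.out = n_grid) * sdlog)
  dens <- stats::dlnorm(x, meanlog, sdlog)
  dx <- diff(x)
  w <- c(dens[1L] * dx[1L] / 2,
         (dens[-c(1L, n_grid)]) * (dx[-1L] + dx[-(n_grid - 1L)]) / 2,
         dens[n_grid] * dx[n_grid - 1L] / 2)
  list(exposure = x, weights = w / sum(w))
}

#' PAF implied by a risk curve and a state exposure summary
#'
#' Dispatches on curve kind: continuous curves integrate over the
#' discretized distribution of the relevant exposure field (`pm25_mean` for
#' ambient PM, `ozone_ppb` for ozone); categorical curves use the exposed
#' proportion (`solid_fuel_prop`).
#'
#' @param curve a risk curve carrying its `risk` label
#'   (`ambient_pm` | `household` | `ozone`).
#' @param exposure an [exposure_summary()].
#' @param cv coefficient of variation for the continuous discretization.
#' @return PAF in \[0, 1).
#' @export
paf_for_state <- function(curve, exposure, cv = 0.25) {
  if (inherits(curve, "risk_curve_categorical")) {
    return(paf_categorical(exposure$solid_fuel_prop, curve$rr_exposed))
  }
  x <- switch(curve$risk,
    ambient_pm = exposure$pm25_mean,
    ozone = exposure$ozone_ppb,
    stop_config(sprintf("no exposure field mapped for risk '%s'", curve$risk))
  )
  dist <- exposure_distribution(x, cv = cv)
  paf_continuous(curve, dist$exposure, dist$weights)
}

#' Scale an envelope by a PAF to get attributable burden
#'
#' Multiplies deaths, YLL and YLD by the PAF row-wise; the DALY column is
#' recomputed as YLL + YLD so the identity is preserved exactly.
#'
#' @param paf fraction in \[0, 1\].
#' @param envelope data.frame with `deaths`, `yll`, `yld` columns (one
#'   cause's rows).
#' @return The envelope with measures scaled and a `daly` column.
#' @export
attributable_burden <- function(paf, envelope) {
  if (paf < 0 || paf > 1) stop_domain("paf must lie in [0, 1]")
  out <- envelope
  out$deaths <- envelope$deaths * paf
  out$yll <- envelope$yll * paf
  out$yld <- envelope$yld * paf
  out$daly <- out$yll + out$yld
  out
}

#' Crude event rate per 100 000 population
#'
#' @param count number of events.
#' @param population persons at risk (> 0).
#' @return events per 100 000.
#' @export
crude_rate <- function(count, population) {
  if (any(population <= 0)) stop_domain("population must be positive")
  count / population * 1e5
}

#' Age-standardised rate
#'
#' Weighted mean of age-specific rates under a standard population:
#' \eqn{\sum_i w_i r_i}. The package default weights (WHO World Standard,
#' normalised to the 5-year grid) ship in
#' `inst/extdata/standard_population.csv`; see [read_standard_population()].
#'
#' @param age_rates per-100 000 rates by age group.
#' @param std_weights standard-population weights (non-negative, sum 1).
#' @return rate per 100 000.
#' @export
age_standardised_rate <- function(age_rates, std_weights) {
  if (length(age_rates) != length(std_weights)) {
    stop_validation("rates and weights must have equal length")
  }
  if (any(std_weights < 0)) stop_validation("weights must be non-negative")
  if (abs(sum(std_weights) - 1) > 1e-9) stop_validation("weights must sum to 1")
  sum(std_weights * age_rates)
}

#' Percent change between two values
#'
#' @param v_start baseline value (non-zero).
#' @param v_end final value.
#' @return `(v_end - v_start) / v_start * 100`.
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start == 0)) stop_domain("percent change undefined for zero baseline")
  (v_end - v_start) / v_start * 100
}

#' Pearson correlation with r-squared and two-sided p value
#'
#' Product-moment correlation between paired values (e.g. crude DALY rates
#' vs per-capita GDP across states), with the p value from the t transform
#' on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, each with
#'   non-zero variance.
#' @return list with `r`, `r2`, `p` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_validation("x and y must have equal length")
  if (length(x) < 3L) stop_validation("need at least 3 paired values")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_validation("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("correlation undefined when a variable has zero variance")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, r2 = r^2, p = p, n = n)
}

#' Recover the PAF implied by an attributable burden table
#'
#' Divides attributable deaths by envelope deaths per state x age x cause x
#' risk cell (cells with a zero envelope are dropped). On synthetic data the
#' recovered PAFs must equal the generating PAFs, which is the
#' burden-inversion property the test suite asserts.
#'
#' @param burden a burden table (see [generate_burden()]).
#' @param envelopes data.frame with `state_id`, `age_group`, `cause`,
#'   `deaths` envelope columns.
#' @return data.frame with `state_id`, `age_group`, `cause`, `risk`, `paf`.
#' @export
recover_paf <- function(burden, envelopes) {
  key <- c("state_id", "age_group", "cause")
  merged <- merge(burden, envelopes[, c(key, "deaths")],
                  by = key, suffixes = c("", "_env"))
  merged <- merged[merged$deaths_env > 0, , drop = FALSE]
  data.frame(
    state_id = merged$state_id, age_group = merged$age_group,
    cause = merged$cause, risk = merged$risk,
    paf = merged$deaths / merged$deaths_env,
    stringsAsFactors = FALSE
  )
}

#' Compute the attributable burden table for a set of panels
#'
#' The analysis-side CRA stage: for every panel, every risk-cause pair in
#' `curves` gets a PAF from the panel's exposure summary ([paf_for_state()])
#' which scales that cause's envelope ([attributable_burden()]).
#'
#' @param panels list of [state_panel()]s.
#' @param curves list of risk curves (each carrying `risk` and `cause`).
#' @param cv exposure-distribution coefficient of variation.
#' @return burden data.frame: `state_id`, `age_group`, `cause`, `risk`,
#'   `deaths`, `yll`, `yld`, `daly`.
#' @export
compute_burden <- function(panels, curves, cv = 0.25) {
  rows <- lapply(panels, function(panel) {
    env <- panel$cause_envelopes
    per_curve <- lapply(curves, function(curve) {
      sub <- env[env$cause == curve$cause, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      paf <- paf_for_state(curve, panel$exposure, cv = cv)
      out <- attributable_burden(paf, sub)
      out$risk <- curve$risk
      out$state_id <- panel$state_id
      out
    })
    do.call(rbind, per_curve)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("state_id", "age_group", "cause", "risk",
          "deaths", "yll", "yld", "daly")]
}
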