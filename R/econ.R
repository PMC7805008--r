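#' Output per worker at baseline
#'
#' Labour share of GDP times GDP, divided by the employed count. GDP is held
#' in US$ millions, so the result is converted to US$ per worker-year.
#'
#' @param economy an [economy_params()].
#' @return US$ per worker-year.
#' @export
output_per_worker <- function(economy) {
  if (economy$employed_count <= 0) stop_domain("employed_count must be positive")
  economy$labour_share * economy$gdp * 1e6 / economy$employed_count
}

#' Expected per-person output at an age and year offset
#'
#' Output per worker grown at the real rate from baseline, weighted by the
#' probability of working at that age, with working-age non-workers credited
#' the non-market share of market output:
#' \deqn{y_0 (1+g)^t [e(a) + (1 - e(a)) s_{nm}]}
#' for `min_working_age <= a < horizon_age`, and 0 outside working ages.
#' Growth applies from `t = 1`; the baseline year pays `y0` exactly.
#'
#' @param age single age in years.
#' @param t year offset from baseline (>= 0).
#' @param economy an [economy_params()].
#' @param employment an [employment_profile()].
#' @return US$ per person-year.
#' @export
expected_output <- function(age, t, economy, employment) {
  if (any(t < 0)) stop_domain("year offset t must be non-negative")
  y0 <- output_per_worker(economy)
  e <- employment_at_age(employment, age)
  working_age <- age >= economy$min_working_age & age < economy$horizon_age
  ifelse(working_age,
         y0 * (1 + economy$growth_rate)^t *
           (e + (1 - e) * economy$nonmarket_share),
         0)
}

#' Present value of lifetime output lost to a death at a given age
#'
#' The human-capital core of the cost-of-illness model: for a death at age
#' `a`, sums expected per-person output over the remainder of working life,
#' weighted by the probability of surviving from `a` to each future age and
#' discounted to the present,
#' \deqn{PV(a) = \sum_{t=0}^{H-1-a} S(a, a+t) (1+r)^{-t} y(a+t, t)}
#' with `H` the retirement horizon. The death year (`t = 0`) counts as a
#' full, undiscounted lost year. Deaths at or beyond the horizon have zero
#' PV; deaths in childhood accrue value once the cohort reaches working age
#' (discounted and survival-adjusted).
#'
#' @param a age at death in years (>= 0).
#' @param economy an [economy_params()].
#' @param employment an [employment_profile()].
#' @param lt a [life_table()].
#' @return US$ (present value at baseline).
#' @export
pv_lost_output <- function(a, economy, employment, lt) {
  if (a < 0) stop_domain("age at death must be non-negative")
  if (a >= economy$horizon_age) return(0)
  t <- 0:(economy$horizon_age - 1L - floor(a))
  s <- survival_probability(lt, a, t)
  disc <- (1 + economy$discount_rate)^(-t)
  y <- expected_output(floor(a) + t, t, economy, employment)
  sum(s * disc * y)
}

# PV schedule over all age-group midpoints of a grid (US$ per death).
pv_schedule <- function(economy, employment, lt, grid = employment$grid) {
  vapply(grid$midpoints, pv_lost_output, numeric(1),
         economy = economy, employment = employment, lt = lt)
}

check_one_state_risk <- function(burden) {
  if (length(unique(burden$state_id)) > 1L) {
    stop_validation("burden rows must come from a single state")
  }
  if (length(unique(burden$risk)) > 1L) {
    stop_validation("burden rows must come from a single risk")
  }
  invisible(burden)
}

#' Mortality loss for one state and risk
#'
#' Attributable deaths in each age group, valued at the present value of
#' lost output for a death at the group's midpoint age, summed over ages
#' and causes.
#'
#' @param burden burden rows restricted to one state and one risk.
#' @param economy,employment,lt the state's economic and demographic inputs.
#' @return US$ millions.
#' @export
mortality_loss <- function(burden, economy, employment, lt) {
  check_one_state_risk(burden)
  grid <- employment$grid
  pv <- stats::setNames(pv_schedule(economy, employment, lt, grid), grid$labels)
  sum(burden$deaths * pv[burden$age_group]) / 1e6
}

#' Morbidity loss for one state and risk
#'
#' Attributable YLDs in each age group valued at the baseline-year expected
#' per-person output at the group midpoint: one YLD costs one expected
#' person-year of output. No discounting and no survival adjustment — the
#' loss is incurred in the baseline year itself.
#'
#' @inheritParams mortality_loss
#' @return US$ millions.
#' @export
morbidity_loss <- function(burden, economy, employment) {
  check_one_state_risk(burden)
  grid <- employment$grid
  y <- stats::setNames(
    vapply(grid$midpoints, expected_output, numeric(1),
           t = 0, economy = economy, employment = employment),
    grid$labels
  )
  sum(burden$yld * y[burden$age_group]) / 1e6
}

#' Loss results for every state and risk
#'
#' Runs [mortality_loss()] and [morbidity_loss()] for each state x risk in
#' the burden table and derives the reporting columns: percent of state GDP
#' and per-capita US$.
#'
#' @param panels list of [state_panel()]s.
#' @param burden attributable-burden table covering those states.
#' @return data.frame of class `loss_result`: `state_id`, `risk`,
#'   `mortality_loss`, `morbidity_loss`, `total_loss` (US$ millions),
#'   `pct_gdp`, `per_capita`, plus `gdp` and `population` carried for
#'   aggregation.
#' @export
compute_losses <- function(panels, burden) {
  names(panels) <- vapply(panels, `[[`, character(1), "state_id")
  rows <- lapply(split(burden, list(burden$state_id, burden$risk), drop = TRUE),
    function(sub) {
      panel <- panels[[sub$state_id[1L]]]
      if (is.null(panel)) {
        stop_validation(sprintf("burden references unknown state '%s'",
                                sub$state_id[1L]))
      }
      mort <- mortality_loss(sub, panel$economy, panel$employment, panel$life_table)
      morb <- morbidity_loss(sub, panel$economy, panel$employment)
      pop <- sum(panel$population)
      data.frame(
        state_id = panel$state_id, risk = sub$risk[1L],
        mortality_loss = mort, morbidity_loss = morb,
        total_loss = mort + morb,
        pct_gdp = pct_of_gdp(mort + morb, panel$economy$gdp),
        per_capita = per_capita(mort + morb, pop),
        gdp = panel$economy$gdp, population = pop,
        stringsAsFactors = FALSE
      )
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loss_result", "data.frame")
  out[order(out$risk, out$state_id), ]
}

#' Discount-rate sensitivity of the loss estimates
#'
#' Recomputes the full mortality + morbidity loss under each discount rate
#' (all other parameters unchanged). Morbidity loss is invariant to the
#' rate; mortality loss is strictly decreasing in it whenever any death
#' occurs below the horizon.
#'
#' @param panels list of [state_panel()]s.
#' @param burden attributable-burden table.
#' @param rates discount rates, each in (0, 1).
#' @return data.frame: one [compute_losses()] block per rate with a
#'   `discount_rate` column.
#' @export
discount_sensitivity <- function(panels, burden, rates) {
  if (!length(rates)) stop_validation("rates must be non-empty")
  if (any(rates <= 0 | rates >= 1)) stop_domain("rates must lie in (0, 1)")
  blocks <- lapply(rates, function(r) {
    repriced <- lapply(panels, function(p) {
      p$economy$discount_rate <- r
      p
    })
    out <- compute_losses(repriced, burden)
    out$discount_rate <- r
    out
  })
  do.call(rbind, blocks)
}
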