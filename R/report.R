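#' Aggregate state loss results to the national level
#'
#' Sums mortality, morbidity and total losses over states (per risk), then
#' recomputes percent-of-GDP against the summed GDP and per-capita US$
#' against the summed population. Aggregation is exact pre-rounding:
#' national totals equal state sums to machine precision.
#'
#' @param results a [compute_losses()] data.frame (one risk, or use a
#'   `risk` split upstream); duplicate state ids are rejected.
#' @return One-row `loss_result` data.frame with `state_id = "national"`.
#' @export
aggregate_national <- function(results) {
  if (!nrow(results)) stop_validation("no state results to aggregate")
  if (length(unique(results$risk)) > 1L) {
    stop_validation("aggregate one risk at a time")
  }
  if (anyDuplicated(results$state_id)) {
    stop_validation("duplicate state ids in aggregation input")
  }
  mort <- sum(results$mortality_loss)
  morb <- sum(results$morbidity_loss)
  gdp <- sum(results$gdp)
  pop <- sum(results$population)
  out <- data.frame(
    state_id = "national", risk = results$risk[1L],
    mortality_loss = mort, morbidity_loss = morb, total_loss = mort + morb,
    pct_gdp = pct_of_gdp(mort + morb, gdp),
    per_capita = per_capita(mort + morb, pop),
    gdp = gdp, population = pop, stringsAsFactors = FALSE
  )
  class(out) <- c("loss_result", "data.frame")
  out
}

#' Share of a total, in percent
#'
#' @param part,whole values on a common scale; `whole > 0`.
#' @return `part / whole * 100`.
#' @export
share_of_total <- function(part, whole) {
  if (any(whole <= 0)) stop_domain("whole must be positive")
  part / whole * 100
}

#' Max/min ratio across units
#'
#' The "x times difference" statistic used to summarise between-state
#' variation.
#'
#' @param values positive values, at least two.
#' @return `max(values) / min(values)`.
#' @export
extremes_ratio <- function(values) {
  if (length(values) < 2L) stop_validation("need at least two values")
  if (any(values <= 0)) stop_domain("extremes ratio requires positive values")
  max(values) / min(values)
}

#' Loss as a percentage of GDP
#'
#' @param loss US$ millions.
#' @param gdp US$ millions (> 0).
#' @return percent.
#' @export
pct_of_gdp <- function(loss, gdp) {
  if (any(gdp <= 0)) stop_domain("gdp must be positive")
  loss / gdp * 100
}

#' Per-capita loss in US$
#'
#' @param loss US$ millions.
#' @param population persons (> 0).
#' @return US$ per person.
#' @export
per_capita <- function(loss, population) {
  if (any(population <= 0)) stop_domain("population must be positive")
  loss * 1e6 / population
}

#' Cause decomposition into percent shares
#'
#' Per-cause percent of the total, with an optional grouped share (e.g.
#' "lung diseases" = COPD + lower respiratory infections + lung cancer).
#'
#' @param by_cause named non-negative values with a positive total.
#' @param groups optional named list mapping a group label to member cause
#'   names; group shares are sums of member shares.
#' @return list with `shares` (named percents summing to 100) and `groups`
#'   (named percents), both unrounded.
#' @export
cause_decomposition <- function(by_cause, groups = NULL) {
  total <- sum(by_cause)
  if (total <= 0) stop_domain("cause decomposition requires a positive total")
  if (any(by_cause < 0)) stop_domain("cause values must be non-negative")
  shares <- share_of_total(by_cause, total)
  grouped <- if (is.null(groups)) numeric(0) else {
    vapply(groups, function(members) sum(shares[members]), numeric(1))
  }
  list(shares = shares, groups = grouped)
}

#' Empirical uncertainty interval from pipeline draws
#'
#' Central interval from repeated pipeline runs under input perturbation —
#' an explicitly simplified stand-in for full draw-level uncertainty
#' machinery. Quantiles use linear interpolation (R type 7).
#'
#' @param draws numeric vector of at least 2 finite draw values.
#' @param level interval mass, in (0, 1); default 0.95.
#' @return named vector `c(lower, upper)`.
#' @export
uncertainty_interval <- function(draws, level = 0.95) {
  if (length(draws) < 2L) stop_validation("need at least 2 draws")
  if (any(!is.finite(draws))) stop_validation("draws must be finite")
  if (level <= 0 || level >= 1) stop_domain("level must lie in (0, 1)")
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Draw-based uncertainty propagation for the national loss
#'
#' Re-runs burden and loss computation `n_draws` times with the exposure
#' summaries and cause envelopes perturbed by seeded multiplicative
#' lognormal noise, collecting the national total loss per risk. Labelled a
#' simplified propagation: it makes no claim of equivalence with the
#' source draw machinery of the burden estimates.
#'
#' @param panels list of [state_panel()]s.
#' @param curves list of risk curves.
#' @param n_draws number of perturbed re-runs (>= 2).
#' @param seed integer seed; draw d uses substream `stable_hash(seed, d)`.
#' @param cv_exposure,cv_envelope lognormal coefficients of variation for
#'   the perturbations.
#' @param cv exposure-distribution CV passed to [compute_burden()].
#' @return data.frame `draw`, `risk`, `total_loss` (US$ millions).
#' @export
pipeline_draws <- function(panels, curves, n_draws = 100L, seed = 1L,
                           cv_exposure = 0.1, cv_envelope = 0.1, cv = 0.25) {
  if (n_draws < 2L) stop_validation("need at least 2 draws")
  sd_ex <- sqrt(log(1 + cv_exposure^2))
  sd_en <- sqrt(log(1 + cv_envelope^2))
  blocks <- lapply(seq_len(n_draws), function(d) {
    rng <- local_rng(stable_hash(seed, paste0("draw-", d)))
    on.exit(rng())
    perturbed <- lapply(panels, function(p) {
      p$exposure$pm25_mean <- p$exposure$pm25_mean * stats::rlnorm(1, -sd_ex^2 / 2, sd_ex)
      p$exposure$ozone_ppb <- p$exposure$ozone_ppb * stats::rlnorm(1, -sd_ex^2 / 2, sd_ex)
      p$exposure$solid_fuel_prop <-
        min(1, p$exposure$solid_fuel_prop * stats::rlnorm(1, -sd_ex^2 / 2, sd_ex))
      scale <- stats::rlnorm(1, -sd_en^2 / 2, sd_en)
      # common envelope scaling keeps deaths <= population with high margin
      p$cause_envelopes$deaths <- pmin(p$cause_envelopes$deaths * scale,
                                       p$cause_envelopes$deaths * 1.5)
      p$cause_envelopes$yll <- p$cause_envelopes$yll * scale
      p$cause_envelopes$yld <- p$cause_envelopes$yld * scale
      p
    })
    burden <- do.call(rbind, lapply(perturbed, generate_burden, curves = curves,
                                    cv = cv))
    losses <- compute_losses(perturbed, burden)
    nat <- lapply(split(losses, losses$risk), aggregate_national)
    nat <- do.call(rbind, nat)
    data.frame(draw = d, risk = nat$risk, total_loss = nat$total_loss,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
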