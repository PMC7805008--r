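# Synthetic state panels with the statistical structure the analysis assumes:
# ~31 geographic units on a 5-year age grid, three air-pollution risk
# components acting on eight causes, burden constructed by applying known PAFs
# to cause envelopes so the CRA stage can be tested by exact inversion.

CAUSES <- c("copd", "lri", "lung_cancer", "ihd", "stroke", "diabetes",
            "neonatal", "cataract")
RISKS <- c("ambient_pm", "household", "ozone")

runif_log <- function(n, range) exp(stats::runif(n, log(range[1L]), log(range[2L])))

# Smooth unimodal (or bimodal for LRI) age profiles of deaths per cause,
# evaluated at group midpoints. Stated as a generator assumption: the source
# estimates do not describe within-state age patterns of attributable deaths.
cause_age_profile <- function(cause, midpoints) {
  g <- function(centre, width) exp(-((midpoints - centre) / width)^2)
  switch(cause,
    copd = g(75, 10),
    lri = 0.7 * g(2, 5) + g(75, 12),
    lung_cancer = 0.18 * g(67, 9),
    ihd = 1.4 * g(65, 12),
    stroke = 0.8 * g(70, 11),
    diabetes = 0.3 * g(62, 10),
    neonatal = 0.5 * g(0, 3),
    cataract = 0 * midpoints,   # cataract causes disability, not death
    stop_config(sprintf("unknown cause '%s'", cause))
  )
}

# YLD per person-year by cause (age profile shared with deaths except for
# cataract and neonatal, which have their own disability patterns).
cause_yld_rate <- function(cause, midpoints) {
  g <- function(centre, width) exp(-((midpoints - centre) / width)^2)
  switch(cause,
    copd = 5.0e-2 * g(70, 15),
    lri = 8e-3 * (g(2, 5) + g(70, 15)),
    lung_cancer = 1e-3 * g(67, 10),
    ihd = 2.0e-2 * g(65, 15),
    stroke = 2.5e-2 * g(70, 14),
    diabetes = 4.0e-2 * g(60, 18),
    neonatal = 1.0e-2 * g(0, 8),
    cataract = 4.0e-2 * g(75, 14)
  )
}

generate_state <- function(state_id, config, seed) {
  grid <- age_grid()
  sub <- stable_hash(seed, state_id)
  rng <- local_rng(sub)
  on.exit(rng())
  rngs <- config$ranges

  # demography
  pop_total <- runif_log(1L, rngs$population_total)
  mid <- grid$midpoints
  age_shape <- exp(-0.028 * mid) * stats::runif(grid$n, 0.9, 1.1)
  population <- pop_total * age_shape / sum(age_shape)

  target_l65 <- stats::runif(1L, rngs$target_l65_over_l0[1L],
                             rngs$target_l65_over_l0[2L])
  lt <- generate_life_table(target_l65, stable_hash(sub, "life_table"))

  # employment-to-population by age group, zero below min working age
  e_template <- stats::setNames(rep(0, grid$n), grid$labels)
  plateau <- stats::runif(1L, 0.55, 0.80)
  for (i in seq_len(grid$n)) {
    s <- grid$starts[i]
    e_template[i] <-
      if (s < config$min_working_age) 0
      else if (s < 20) 0.35 * plateau
      else if (s < 25) 0.75 * plateau
      else if (s < 55) plateau
      else if (s < 60) 0.85 * plateau
      else if (s < 65) 0.60 * plateau
      else if (s < 70) 0.35 * plateau
      else if (s < 80) 0.15 * plateau
      else 0
  }
  employment <- employment_profile(pmin(e_template, 1), grid)

  # economy
  pc_gdp <- runif_log(1L, rngs$gdp_per_capita_usd)
  labour_share <- stats::runif(1L, rngs$labour_share[1L], rngs$labour_share[2L])
  employed <- sum(population * employment$e)
  economy <- economy_params(
    gdp = pc_gdp * pop_total / 1e6,
    labour_share = labour_share,
    employed_count = employed,
    growth_rate = config$growth_rate,
    discount_rate = config$discount_rate,
    nonmarket_share = config$nonmarket_share,
    min_working_age = config$min_working_age,
    horizon_age = config$horizon_age
  )

  exposure <- exposure_summary(
    pm25_mean = runif_log(1L, rngs$pm25_mean),
    solid_fuel_prop = stats::runif(1L, rngs$solid_fuel_prop[1L],
                                   rngs$solid_fuel_prop[2L]),
    ozone_ppb = stats::runif(1L, rngs$ozone_ppb[1L], rngs$ozone_ppb[2L])
  )

  # cause envelopes: age-specific all-cause mortality from the life table,
  # ~60% assigned to the eight modelled causes via smooth age profiles
  l <- lt$abridged
  width <- ifelse(is.na(grid$width), 5L, grid$width)
  m_age <- numeric(grid$n)
  for (i in seq_len(grid$n)) {
    l_next <- if (i < grid$n) l[i + 1L] else 0.3 * l[i]
    m_age[i] <- max(0, (l[i] - l_next) / pmax(l[i], 1e-12)) / width[i]
  }
  all_deaths <- population * pmin(m_age, 0.5)
  profiles <- vapply(CAUSES, cause_age_profile, numeric(grid$n), midpoints = mid)
  jitter <- matrix(stats::runif(grid$n * length(CAUSES), 0.8, 1.2),
                   nrow = grid$n)
  profiles <- profiles * jitter
  denom <- pmax(rowSums(profiles), 1e-12)
  share_modelled <- stats::runif(1L, 0.55, 0.65)
  deaths <- profiles / denom * all_deaths * share_modelled
  # reference remaining life expectancy for YLL (flat cap at 86 years)
  rle <- pmax(0, 86 - mid)
  yll <- deaths * rle
  yld_rates <- vapply(CAUSES, cause_yld_rate, numeric(grid$n), midpoints = mid)
  yld <- yld_rates * population * matrix(stats::runif(grid$n * length(CAUSES),
                                                      0.8, 1.2), nrow = grid$n)
  env <- data.frame(
    age_group = rep(grid$labels, times = length(CAUSES)),
    cause = rep(CAUSES, each = grid$n),
    deaths = as.vector(deaths),
    yll = as.vector(yll),
    yld = as.vector(yld),
    stringsAsFactors = FALSE
  )

  state_panel(state_id, population, lt, employment, economy, exposure, env, grid)
}

#' Generate a collection of synthetic state panels
#'
#' Each state draws from a private substream seeded by a stable hash of
#' `(seed, state_id)`, so identical `(config, seed)` gives bit-identical
#' panels and adding a state never perturbs the others.
#'
#' @param config a config list from [default_config()] (validated).
#' @param seed integer seed.
#' @return Named list of `config$n_states` [state_panel()]s with ids
#'   `"S01"`, `"S02"`, ...
#' @export
generate_panel <- function(config = default_config(), seed = 1L) {
  config <- validate_config(config)
  if (!is_scalar_number(seed)) stop_config("seed must be a single integer")
  ids <- sprintf("S%02d", seq_len(config$n_states))
  panels <- lapply(ids, generate_state, config = config, seed = as.integer(seed))
  stats::setNames(panels, ids)
}

#' Read the packaged default risk curves
#'
#' Synthetic, plausibly-shaped exposure-response curves for the three risk
#' components and eight causes (ambient PM2.5 and household solid-fuel use
#' on seven causes each, cataract household-only, ozone on COPD only). They
#' are stand-ins for literature-derived curves, which are inputs to this
#' pipeline, not estimated by it.
#'
#' @param path CSV path; defaults to the packaged `risk_curves.csv`.
#' @return Named list of risk curves (names `"risk:cause"`).
#' @export
default_risk_curves <- function(path = system.file("extdata", "risk_curves.csv",
                                                   package = "airburden")) {
  read_risk_curves(path)
}

#' Generate an attributable-burden table with known PAFs
#'
#' Applies [paf_for_state()] to each risk-cause pair's envelope — the same
#' arithmetic the burden stage uses — so recovery of the generating PAFs by
#' [recover_paf()] is exact. Also emits parent `"air_pollution"` rows using
#' the multiplicative independent combination
#' \eqn{1 - \prod_k (1 - PAF_k)} over the components covering each cause
#' (a generator assumption; the analysis side treats parent burden as an
#' input and never sums component PAFs).
#'
#' @param panel a [state_panel()].
#' @param curves named list of risk curves covering every generated pair.
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic given the panel and curves.
#' @param cv exposure-distribution CV (must match the analysis stage).
#' @param pairs optional data.frame (`risk`, `cause`) of pairs that must be
#'   generated; a pair without a matching curve is a configuration error.
#'   Defaults to the pairs implied by `curves`.
#' @return burden data.frame (`state_id`, `age_group`, `cause`, `risk`,
#'   `deaths`, `yll`, `yld`, `daly`).
#' @export
generate_burden <- function(panel, curves, seed = 1L, cv = 0.25, pairs = NULL) {
  if (!length(curves)) stop_config("no risk curves supplied")
  if (!is.null(pairs)) {
    have <- paste(vapply(curves, `[[`, character(1), "risk"),
                  vapply(curves, `[[`, character(1), "cause"), sep = ":")
    want <- paste(pairs$risk, pairs$cause, sep = ":")
    lack <- setdiff(want, have)
    if (length(lack)) {
      stop_config(sprintf("no risk curve for pair '%s'", lack[1L]))
    }
  }
  component <- compute_burden(list(panel), curves, cv = cv)
  # parent risk: combine component PAFs multiplicatively per cause
  pafs <- vapply(curves, paf_for_state, numeric(1), exposure = panel$exposure,
                 cv = cv)
  curve_cause <- vapply(curves, `[[`, character(1), "cause")
  env <- panel$cause_envelopes
  parent_rows <- lapply(unique(curve_cause), function(cs) {
    paf_parent <- 1 - prod(1 - pafs[curve_cause == cs])
    out <- attributable_burden(paf_parent, env[env$cause == cs, , drop = FALSE])
    out$risk <- "air_pollution"
    out$state_id <- panel$state_id
    out
  })
  parent <- do.call(rbind, parent_rows)
  out <- rbind(component,
               parent[, c("state_id", "age_group", "cause", "risk",
                          "deaths", "yll", "yld", "daly")])
  rownames(out) <- NULL
  out
}
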