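# Shared fixture builders. Everything is constructed in code at test time;
# the only files touched are tempdirs.

# Small config for fast tests (acceptance tests use the full default).
test_config <- function(n_states = 3L) {
  config <- default_config()
  config$n_states <- as.integer(n_states)
  config
}

# Flat survivorship: S(a, a+t) = 1 everywhere.
flat_life_table <- function(max_age = 100L) {
  life_table(rep(1e5, max_age + 1L))
}

# Everyone works at every age group.
full_employment <- function(grid = age_grid()) {
  employment_profile(rep(1, grid$n), grid)
}

# Economy with a chosen baseline output per worker y0 (US$/worker-year).
economy_with_y0 <- function(y0, growth_rate = 0, discount_rate = 0.06,
                            nonmarket_share = 0.3, min_working_age = 0L,
                            horizon_age = 65L) {
  economy_params(gdp = 1, labour_share = 0.5,
                 employed_count = 0.5 * 1e6 / y0,
                 growth_rate = growth_rate, discount_rate = discount_rate,
                 nonmarket_share = nonmarket_share,
                 min_working_age = min_working_age, horizon_age = horizon_age)
}

# A minimal continuous curve: RR 1 at tmrel, rising linearly to rr_hi at hi.
toy_curve <- function(tmrel = 0, hi = 10, rr_hi = 2, risk = "ambient_pm",
                      cause = "copd") {
  risk_curve_continuous(c(tmrel, hi), c(1, rr_hi), tmrel = tmrel,
                        risk = risk, cause = cause)
}

# Cached small panel set so multiple tests can share one generation run.
cached_panels <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_panel(test_config(3L), seed = 42L)
    cache
  }
})

cached_curves <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_risk_curves()
    cache
  }
})
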