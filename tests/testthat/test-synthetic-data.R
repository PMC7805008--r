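test_that("generate_panel honours count, ids and determinism contracts", {
  config <- test_config(2L)
  panels <- generate_panel(config, seed = 7L)
  expect_length(panels, 2L)
  expect_equal(length(unique(vapply(panels, `[[`, character(1), "state_id"))), 2L)

  again <- generate_panel(config, seed = 7L)
  expect_identical(serialize(panels, NULL), serialize(again, NULL))

  other_seed <- generate_panel(config, seed = 8L)
  expect_false(identical(serialize(panels, NULL), serialize(other_seed, NULL)))

  bad <- config
  bad$n_states <- 0L
  expect_error(generate_panel(bad, 1L), class = "airburden_config_error")
  bad2 <- config
  bad2$ranges$pm25_mean <- c(10, -5)
  expect_error(generate_panel(bad2, 1L), class = "airburden_config_error")
})

test_that("adding a state never perturbs existing states (substreams)", {
  p3 <- generate_panel(test_config(3L), seed = 11L)
  p5 <- generate_panel(test_config(5L), seed = 11L)
  expect_identical(serialize(p3[["S02"]], NULL), serialize(p5[["S02"]], NULL))
})

test_that("generated panels satisfy every type invariant", {
  panels <- cached_panels()
  for (p in panels) {
    expect_silent(validate_panel(p))
    expect_true(all(p$population >= 0))
    expect_true(all(diff(p$life_table$l) <= 1e-9))
    expect_true(p$life_table$l[1L] > 0)
    expect_true(all(p$employment$e >= 0 & p$employment$e <= 1))
    below <- p$grid$starts + 5L <= p$economy$min_working_age
    expect_true(all(p$employment$e[below] == 0))
    deaths_by_age <- tapply(p$cause_envelopes$deaths, p$cause_envelopes$age_group, sum)
    pop <- stats::setNames(p$population, p$grid$labels)
    expect_true(all(deaths_by_age <= pop[names(deaths_by_age)] + 1e-9))
    expect_true(all(p$cause_envelopes$yll >= 0))
    expect_true(all(p$cause_envelopes$yld >= 0))
  }
})

test_that("generate_life_table meets its target and monotonicity contracts", {
  for (target in c(0.35, 0.6, 0.8)) {
    lt <- generate_life_table(target, seed = 3L)
    expect_true(all(diff(lt$l) <= 0))
    expect_equal(survival_probability(lt, 0, 65), target, tolerance = 0.02)
  }
  # near-flat limit: survival close to 1 for all horizons up to 65
  lt <- generate_life_table(0.999, seed = 5L)
  s <- vapply(0:64, function(a) survival_probability(lt, a, 65 - a), numeric(1))
  expect_true(all(s > 0.995))
  expect_error(generate_life_table(1.2, 1L), class = "airburden_domain_error")
  expect_error(generate_life_table(0, 1L), class = "airburden_domain_error")
})

test_that("generate_burden applies known PAFs exactly", {
  panel <- cached_panels()[[1L]]
  curves <- cached_curves()
  burden <- generate_burden(panel, curves, seed = 1L)

  # null curve: RR identically 1 => zero attributable burden for the pair
  null_curve <- risk_curve_continuous(c(0, 300), c(1, 1), tmrel = 0,
                                      risk = "ambient_pm", cause = "copd")
  b0 <- generate_burden(panel, list(null_curve), seed = 1L)
  comp0 <- b0[b0$risk == "ambient_pm", ]
  expect_true(all(comp0$deaths == 0))
  expect_true(all(comp0$daly == 0))

  # zero envelopes => all-zero burden
  zero_panel <- panel
  zero_panel$cause_envelopes$deaths <- 0
  zero_panel$cause_envelopes$yll <- 0
  zero_panel$cause_envelopes$yld <- 0
  bz <- generate_burden(zero_panel, curves, seed = 1L)
  expect_true(all(bz[, c("deaths", "yll", "yld", "daly")] == 0))

  # missing curve for a requested pair is a configuration error
  pairs <- data.frame(risk = "ozone", cause = "stroke")
  expect_error(generate_burden(panel, curves, pairs = pairs),
               class = "airburden_config_error")

  # DALY identity holds record-wise
  expect_equal(burden$daly, burden$yll + burden$yld, tolerance = 1e-12)
})

test_that("burden generation inverts: recovered PAFs equal generating PAFs", {
  panels <- cached_panels()
  curves <- cached_curves()
  for (panel in panels) {
    burden <- generate_burden(panel, curves, seed = 1L)
    env <- cbind(state_id = panel$state_id, panel$cause_envelopes)
    rec <- recover_paf(burden[burden$risk != "air_pollution", ], env)
    gen <- vapply(curves, paf_for_state, numeric(1), exposure = panel$exposure)
    key <- paste(vapply(curves, `[[`, character(1), "risk"),
                 vapply(curves, `[[`, character(1), "cause"), sep = ":")
    expected <- stats::setNames(gen, key)[paste(rec$risk, rec$cause, sep = ":")]
    expect_equal(rec$paf, unname(expected), tolerance = 1e-9)
  }
})
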