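# Independent piecewise-linear RR oracle: own interpolation, never calls
# relative_risk().
oracle_rr <- function(exposure_knots, rr_knots, tmrel, x) {
  if (x <= tmrel) return(1)
  if (x >= exposure_knots[length(exposure_knots)]) {
    return(rr_knots[length(rr_knots)])
  }
  i <- max(which(exposure_knots <= x))
  x0 <- exposure_knots[i]; x1 <- exposure_knots[i + 1L]
  r0 <- rr_knots[i]; r1 <- rr_knots[i + 1L]
  r0 + (r1 - r0) * (x - x0) / (x1 - x0)
}

test_that("relative_risk: TMREL, interpolation and plateau", {
  curve <- risk_curve_continuous(c(5, 10, 20), c(1, 1.2, 1.4), tmrel = 5)
  expect_identical(relative_risk(curve, 5), 1)
  expect_identical(relative_risk(curve, 2), 1)
  expect_equal(relative_risk(curve, 15), 1.3)   # midway between knots
  expect_equal(relative_risk(curve, 50), 1.4)   # plateau beyond last knot
  expect_error(relative_risk(risk_curve_categorical(2), 5),
               class = "airburden_type_error")
  expect_error(relative_risk(curve, -1), class = "airburden_domain_error")
})

test_that("paf_continuous matches hand-computed and degenerate cases", {
  curve <- toy_curve(tmrel = 0, hi = 10, rr_hi = 2)
  # point mass at tmrel
  expect_equal(paf_continuous(curve, 0, 1), 0)
  # point mass at RR = 2 => 0.5
  expect_equal(paf_continuous(curve, 10, 1), 0.5)
  # two-point: RRs (1, 3) with equal weight => Rbar = 2, PAF = 0.5
  curve3 <- risk_curve_continuous(c(0, 10), c(1, 3), tmrel = 0)
  expect_equal(paf_continuous(curve3, c(0, 10), c(0.5, 0.5)), 0.5)
  expect_error(paf_continuous(curve, c(0, 10), c(0.6, 0.6)),
               class = "airburden_validation_error")
  expect_error(paf_continuous(curve, c(0, 10), c(-0.5, 1.5)),
               class = "airburden_validation_error")
})

test_that("paf_continuous equals a brute-force oracle on random distributions", {
  set.seed(101)
  for (rep in 1:1000) {
    n_knots <- sample(3:6, 1L)
    knots <- sort(stats::runif(n_knots, 0, 100))
    knots <- knots + seq_len(n_knots) * 1e-6      # ensure strictly increasing
    rrs <- cumsum(c(1, stats::runif(n_knots - 1L, 0, 0.5)))
    tmrel <- knots[1L]
    curve <- risk_curve_continuous(knots, rrs, tmrel = tmrel)
    x <- stats::runif(10L, 0, 120)
    w <- stats::runif(10L)
    w <- w / sum(w)
    rbar <- 0
    for (i in 1:10) rbar <- rbar + w[i] * oracle_rr(curve$exposure, curve$rr, tmrel, x[i])
    expect_equal(paf_continuous(curve, x, w), (rbar - 1) / rbar,
                 tolerance = 1e-12)
  }
})

test_that("paf_categorical formula, bounds and consistency with continuous", {
  expect_equal(paf_categorical(0, 5), 0)
  expect_equal(paf_categorical(0.5, 3), 0.5)
  expect_equal(paf_categorical(1, 2), 0.5)
  # consistency: p = 1 equals a continuous point mass at the exposed RR
  curve <- toy_curve(tmrel = 0, hi = 10, rr_hi = 2)
  expect_identical(paf_categorical(1, 2), paf_continuous(curve, 10, 1))
  expect_error(paf_categorical(0.5, 0.8), class = "airburden_domain_error")
  expect_error(paf_categorical(1.2, 2), class = "airburden_domain_error")
})

test_that("PAF bounds and monotonicity properties hold over random cases", {
  set.seed(202)
  for (rep in 1:200) {
    rr <- 1 + stats::rexp(1L)
    p <- stats::runif(1L)
    paf <- paf_categorical(p, rr)
    expect_true(paf >= 0 && paf < 1)
    # monotone in p and in rr
    expect_true(paf_categorical(min(1, p + 0.1), rr) >= paf)
    expect_true(paf_categorical(p, rr + 0.5) >= paf)
  }
  # PAF = 0 iff Rbar = 1
  curve <- toy_curve()
  expect_identical(paf_continuous(curve, 0, 1), 0)
  expect_gt(paf_continuous(curve, c(0, 5), c(0.9, 0.1)), 0)
  # monotone in a knot RR
  lo <- paf_continuous(toy_curve(rr_hi = 1.5), 7, 1)
  hi <- paf_continuous(toy_curve(rr_hi = 2.5), 7, 1)
  expect_gt(hi, lo)
})

test_that("attributable_burden scales measures and preserves the DALY identity", {
  env <- data.frame(age_group = c("60-64", "65-69"), cause = "copd",
                    deaths = c(100, 50), yll = c(2000, 800), yld = c(300, 120))
  out <- attributable_burden(0.25, env)
  expect_equal(out$deaths, c(25, 12.5))
  expect_equal(out$daly, out$yll + out$yld)
  expect_true(all(attributable_burden(0, env)$daly == 0))
  expect_equal(attributable_burden(1, env)$deaths, env$deaths)
  expect_error(attributable_burden(1.5, env), class = "airburden_domain_error")
})

test_that("rates, percent change and correlation behave per contract", {
  expect_equal(crude_rate(100, 1e6), 10)
  expect_equal(crude_rate(0, 123), 0)
  expect_equal(crude_rate(1.67e6, 1.39e9), 120.14388, tolerance = 1e-6)
  expect_error(crude_rate(5, 0), class = "airburden_domain_error")

  expect_equal(age_standardised_rate(c(10, 20), c(0.25, 0.75)), 17.5)
  expect_equal(age_standardised_rate(c(5, 500), c(1, 0)), 5)
  expect_equal(age_standardised_rate(rep(7, 4), rep(0.25, 4)), 7)
  expect_error(age_standardised_rate(c(1, 2), c(0.5, 0.4)),
               class = "airburden_validation_error")
  expect_error(age_standardised_rate(c(1, 2, 3), c(0.5, 0.5)),
               class = "airburden_validation_error")

  expect_equal(percent_change(10, 20), 100)
  expect_equal(percent_change(20, 20), 0)
  expect_equal(percent_change(50, 17.9), -64.2)
  expect_error(percent_change(0, 5), class = "airburden_domain_error")

  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  res <- pearson_correlation(c(1, 2, 3, 5), c(2, 1.8, 1.2, 0.9))
  expect_equal(res$r2, res$r^2)
  ct <- stats::cor.test(c(1, 2, 3, 5), c(2, 1.8, 1.2, 0.9))
  expect_equal(res$p, ct$p.value)
  # a correlation of -0.71 reports r^2 rounding to 0.50
  expect_equal(round_half_up((-0.71)^2, 2), 0.50)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
               class = "airburden_domain_error")
  expect_error(pearson_correlation(1:2, 2:3),
               class = "airburden_validation_error")
})

test_that("standard population weights load normalised on the default grid", {
  w <- read_standard_population()
  expect_equal(sum(w), 1)
  expect_setequal(names(w), age_grid()$labels)
})
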