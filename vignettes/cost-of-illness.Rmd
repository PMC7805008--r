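---
title: "Attributable burden and the output-based cost of illness: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable burden and the output-based cost of illness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airburden)
```

## The problem

Ambient fine particulate matter (PM₂.₅), household air pollution from solid
cooking fuels, and ambient ozone are leading environmental risk factors in
low- and middle-income settings. Two questions are asked of them at the
state level: how much death and disability do they cause (attributable
burden), and what does that burden cost the economy in lost output
(cost of illness)? `airburden` implements both stages as a pipeline over a
panel of geographic units, each carrying demography, a life table, an
employment profile, macro-economic parameters, exposure summaries and
cause-specific burden envelopes.

## Attributable burden

For each risk-cause pair a relative-risk curve maps exposure to RR, with
RR = 1 at and below the theoretical minimum-risk exposure level (TMREL).
The population attributable fraction is `(R̄ − 1)/R̄` with
`R̄ = Σ wᵢ RR(xᵢ)` for continuous exposures and
`p(RR − 1)/(1 + p(RR − 1))` for the categorical solid-fuel exposure. The
PAF multiplies the cause's envelope of deaths, YLLs and YLDs; DALYs are
recomputed as YLL + YLD so the identity is exact record-wise.

Design choices made where the design was genuinely open:

- **Piecewise-linear RR interpolation with plateau extrapolation.** Smooth
  splines were rejected deliberately: a piecewise-linear curve admits an
  exact independent summation oracle, so the PAF integration can be tested
  to 1e-12 rather than to a quadrature tolerance.
- **Exposure distribution from a summary mean.** State exposure arrives as
  a single population-weighted mean. `exposure_distribution()` spreads it
  as a lognormal with configurable coefficient of variation (default 0.25,
  a typical within-region spread for annual PM₂.₅) discretized on a fixed
  multiplicative grid with trapezoidal weights, preserving the arithmetic
  mean; `cv = 0` degenerates to a point mass. A fixed grid keeps the
  integral reproducible and lets the generator and the analysis stage share
  one deterministic function, which makes burden-stage inversion exact.
- **No renormalisation of component PAFs.** Component risks (ambient PM,
  household, ozone) can attribute overlapping burden; their PAFs may sum to
  more than the parent air-pollution PAF even under independence. The
  parent is therefore a separate derivation (in the generator: the
  multiplicative combination `1 − Π(1 − PAFₖ)`, a labelled assumption) and
  is never reconstructed from component sums.
- **Non-age-specific risk curves.** Published practice fits age-specific
  curves for the cardiovascular causes; curve fitting is out of scope here
  (curves are inputs), so a single curve per risk-cause pair is used. The
  inversion and valuation machinery is indifferent to this choice.
- **Standard population.** The source of the age-standardisation weights
  used upstream is not stated in the text this package follows;
  `age_standardised_rate()` therefore takes weights as an argument, and the
  package ships the WHO World Standard on the 5-year grid as a documented
  default.

## The economic model

Output per worker at baseline is `y₀ = labour_share × GDP / employed`.
Expected per-person output at age `a`, `t` years ahead, is

```
y(a, t) = y₀ (1+g)ᵗ [e(a) + (1 − e(a)) s]   for  A_min ≤ a < H,  else 0
```

with `e(a)` the employment-to-population ratio, `s` the non-market share
(default 0.30), `A_min` the minimum working age (default 15) and `H` the
retirement horizon (default 65). A death at age `a` costs

```
PV(a) = Σ_{t=0}^{H−1−a} S(a, a+t) (1+r)⁻ᵗ y(a+t, t)
```

and one YLD costs `y(a, 0)`: morbidity is a single-year, undiscounted,
survival-free loss by construction.

Numerical and convention choices, each surfaced as a config knob:

- **The death year counts.** `t = 0` is a full, undiscounted lost year,
  symmetric with the morbidity valuation (which is entirely a `t = 0`
  quantity). The alternative (losses start the following year) would scale
  every PV by roughly `1/(1+r)`.
- **Retirement horizon.** "The remainder of working life" is bounded above
  at `H = 65` by default; no printed retirement age exists in the source
  text, making this the largest open convention in the model. Deaths at or
  beyond `H` carry zero PV; child deaths carry discounted, survival-adjusted
  future working-life value because `y(a, t)` is zero until `A_min` but the
  sum runs from the death age.
- **Midpoint age assignment.** Deaths within a 5-year group are valued at
  the group's integer midpoint (62 for 60–64); the terminal open group's
  midpoint is inert under the default horizon.
- **Growth from t = 1.** The baseline year pays `y₀` exactly; growth
  compounds from the following year.
- **Precision.** All aggregation is in full double precision in US$
  millions; half-up rounding happens only at the reporting layer
  (`round_half_up()`), matching the convention of printed tables.

Monotonicity properties (PV decreasing in `r`, increasing in `g` and `H`;
morbidity invariant to `r` and the life table) are asserted as tests, and
the PV sum is checked against the closed-form geometric series
`y₀(1 − ρᵀ)/(1 − ρ)`, `ρ = (1+g)/(1+r)`, under flat survival and full
employment, to 1e-10.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces ~31 units on the 5-year grid 0–95+ with:
log-uniform total population (0.3M–230M) and per-capita GDP ($600–$5500),
spanning the between-state magnitudes typical of Indian states; exposure
draws over the observed ranges (PM₂.₅ 16–218 µg/m³ log-uniform, solid-fuel
use 5–85%, ozone 47–77 ppb); a Gompertz–Makeham life table rescaled so
survival to 65 hits a drawn target exactly; a plateau-shaped employment
profile, zero below the minimum working age; and cause envelopes whose age
pattern follows the life-table hazard, with ~60% of all deaths assigned to
the eight modelled causes via smooth unimodal age profiles (a stated
assumption: the source text does not describe within-state age patterns of
attributable deaths). YLD rates are set so the attributable YLD-per-death
ratio lands near 3–5, the order observed in burden studies, making the
morbidity share of total loss ~15%.

Seeding uses one global integer; each state (and each uncertainty draw)
derives a private substream by a stable polynomial hash of
`(seed, label)`, so identical inputs are bit-identical and adding a state
never perturbs the others.

The generator does **not** attempt to reproduce actual state demography,
satellite-derived exposure fields, or fitted risk curves, and its
attributable share of total deaths (~30% at default settings) runs above
the published ~18% because exposures, demography and development level are
drawn independently rather than jointly. Consequently a green test
establishes the *arithmetic* of the pipeline — PAF inversion, valuation
identities, aggregation conservation, sensitivity ordering — not the
magnitudes of any real-world estimate.

## Uncertainty

`pipeline_draws()` re-runs burden and valuation under seeded multiplicative
lognormal perturbations of exposures and envelopes (default CV 0.10 each)
and `uncertainty_interval()` takes central empirical quantiles with linear
interpolation. This is an explicitly simplified stand-in for the
draw-level machinery behind published uncertainty intervals, which mixes
exposure, relative-risk and demographic uncertainty in proportions not
recoverable from the text; no equivalence is claimed, and the output is
labelled accordingly.

## Verification of published arithmetic

`verify_paper_arithmetic()` recomputes every headline identity that is
recomputable from printed constants alone (shares of total deaths and
DALYs, the mortality + morbidity sum, extremes ratios, the lung-disease
cause grouping, the health-care cost cross-product, r², and the
percent-of-GDP and per-capita derivations against constants implied by
printed pairs — computed at run time, never hard-coded), comparing at
printed precision with half-up rounding. State-column sums are checked
against the national row within half a printed unit per state. Two printed
shares are *not* recomputable from their own rounded inputs (the total DALY
share and the lung-disease share of economic loss, each off by 0.1
percentage points due to rounding propagation); they are documented rather
than forced, and excluded from the pass/fail set.

## Known limitations

- Employment profiles are held at baseline (no cohort projection), and one
  growth rate applies to all states.
- The morbidity valuation prices a YLD at a full expected person-year of
  output, the standard but conservative-in-both-directions convention.
- Health-care (direct) costs, willingness-to-pay welfare valuation, and
  exposure estimation from raw data are out of scope.
- The parent-risk combination in the generator assumes independent
  components; real mediation between ambient and household PM₂.₅ is not
  modelled.
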