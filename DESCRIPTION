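Package: airburden
Title: Attributable Burden and Cost-of-Illness Analysis of Air Pollution
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for state-level comparative-risk-assessment
    arithmetic and output-based cost-of-illness valuation of air pollution.
    Computes population attributable fractions from relative-risk curves and
    exposure summaries, applies them to cause-specific death/YLL/YLD envelopes,
    and values the attributable burden as the survival-adjusted present
    discounted value of lost market and non-market output (premature
    mortality) plus single-year lost output per YLD (morbidity). Includes a
    seeded synthetic-data generator for the full input panel, national
    aggregation with percent-of-GDP and per-capita reporting, discount-rate
    sensitivity analysis, simplified draw-based uncertainty intervals, and a
    command-line interface for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
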