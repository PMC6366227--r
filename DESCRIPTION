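Package: socialign
Title: Susceptibility to Social Influence in Face Evaluation: Task Design,
    Choice Modelling and Meta-Analytic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how much people align their judgements with a
    group opinion in a two-phase face-evaluation task, and how that
    susceptibility relates to perceived childhood environmental adversity.
    Provides the trial schedule and bogus group-feedback generator (12
    disagreement, 6 agreement and 6 no-feedback trials over 24 faces), a
    synthetic cohort simulator with a known adversity-to-influence link,
    questionnaire composite scoring (unpredictability, harshness, their
    z-score sum), social alignment scores, Cronbach's alpha and
    interquartile-range screening, a two-parameter discrete-Gaussian choice
    model (social-influence weight delta, internal noise sigma) with
    multi-start maximum-likelihood fitting and a grid-search oracle,
    participant-level regressions with Cook's-distance slope-outlier
    filtering, inverse-variance fixed-effects meta-analysis with
    heterogeneity Q, and an end-to-end pipeline runner over delimited text
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
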