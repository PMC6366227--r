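---
title: "Modelling susceptibility to social influence: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling susceptibility to social influence: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialign)
```

## The task and what the package computes

In a two-phase face-evaluation task, participants rate 24 unfamiliar faces
on an 8-point approachability scale, then see each face again together with
the (bogus) modal rating of a peer group and rate it a second time. The
feedback design is fixed: of the 24 faces, 12 receive disagreeing group
ratings — three each at −3, −2, +2 and +3 scale points from the
participant's initial rating — 6 receive an agreeing rating, and 6 no
feedback at all. `build_schedule()` assigns this condition multiset to faces
by a uniform random permutation; `compute_feedback()` produces the displayed
group rating, clipping at the scale edges and flagging when clipping changed
the displayed deviation (the original online procedure is not documented on
this point, so the edge case is made explicit and auditable rather than
hidden).

Susceptibility to social influence is summarised behaviourally by the
*social alignment score*: the mean rating change (post-test minus test) per
disagreement condition, sign-flipped in the negative conditions so that
positive values always mean movement *towards* the group
(`mean_rating_change()`, `social_alignment()`).

## The choice model

The two-parameter model treats the post-test rating as a discretized normal
around a weighted compromise between one's own and the group's rating:

$$\mu = x_\mathrm{ini}\,(1-\delta) + x_\mathrm{group}\,\delta,
\qquad
p(x) = \Phi\!\left(x+\tfrac12;\,\mu,\sigma\right) -
       \Phi\!\left(x-\tfrac12;\,\mu,\sigma\right),\; x \in \{1,\dots,8\},$$

where $\delta$ is the weight given to the group (0 = ignore, 1 = adopt;
negative values capture contrarian adjustment away from the group) and
$\sigma$ is the internal noise, in rating units. Three numerical choices
deserve note:

* **Scale edges.** The interval formula leaves tail mass outside the 1..8
  scale. We absorb it into the boundary ratings ($p(1)$ integrates from
  $-\infty$, $p(8)$ to $+\infty$), so the pmf sums to 1 exactly for every
  $(\mu, \sigma)$ — an alternative would be renormalizing the interior
  differences, which distorts probabilities asymmetrically near the edges.
* **Trials entering the likelihood.** Disagreement and agreement trials
  carry a group rating and enter the likelihood (18 per participant);
  no-feedback trials have none and are excluded. Since agreement implies
  $x_\mathrm{group} = x_\mathrm{ini}$, those trials constrain only
  $\sigma$, never $\delta$ (a property asserted numerically in the tests).
* **Probability floor.** Log-probabilities are floored at $\log(10^{-300})$
  so the objective stays finite at extreme parameter values.

`fit_participant()` minimizes the negative log-likelihood with bounded
L-BFGS-B from a fixed interior grid of starts (default 5 × 5), keeping the
best endpoint; convergence tolerance is the optimizer's default
(`factr = 1e7`, i.e. ~1e-9 relative). Bounds default to $\delta \in [-1,
1]$ and $\sigma \in [0.05, 5]$: wide enough for any observed behaviour,
tight enough to keep the likelihood well conditioned. Because a single
gradient start can stall on a likelihood this lumpy (the data are 18
integers), the package also ships `fit_oracle_grid()`, an exhaustive
grid-search used in the tests to certify that the optimizer's optimum is at
least as good as a 0.01-step grid scan.

`predict_alignment()` maps a fit back to the behavioural summary: the
expected post-test rating under the fitted pmf gives a predicted rating
change per trial, aggregated and sign-flipped exactly like the observed
alignment scores, so model and behaviour are directly comparable.

## Environment scores

Childhood unpredictability is the mean of three 1–7 household-chaos items;
childhood harshness is the mean of three reverse-coded (8 − response)
perceived-wealth items. Both composites are z-scored against the analysed
cohort and *adversity* is their exact sum. Two conventions are fixed
because results depend on them:

* **Order of operations.** z-scoring uses the full quality-checked cohort
  and is *not* recomputed after outlier exclusion; the 1.5 × IQR screens
  (first on the overall alignment score, then on the unpredictability
  z-score) therefore operate on stable scores, and the run log reports both
  screens' counts.
* **Quartile definition.** The IQR fences use linearly interpolated
  quantiles (R's type 7). Exclusion counts can differ under other quantile
  types, so the choice is part of the contract.

Internal consistency is computed by `cronbach_alpha()` with the standard
variance decomposition (n − 1 denominators).

## The synthetic cohort generator

`simulate_cohort()` produces a cohort in which every downstream stage has a
known ground truth. It emulates the study conditions, not any particular
dataset:

* **Questionnaires.** Each participant has a pair of latent traits with
  correlation 0.50. Participants in the lower third of the unpredictability
  trait (threshold `qnorm(p_zero_unpredictability)`, default 1/3) report no
  unpredictability at all — items (1, 1, 1) — making the zero-inflated
  group the genuinely low-trait group rather than an independent coin flip;
  the rest answer around a positively-skewed transform of the trait.
  Harshness traits follow a two-component normal mixture (via a monotone
  quantile map, so the latent correlation is preserved), yielding the
  negatively-skewed/bimodal reversed-score distribution typical of
  perceived-wealth items. Item noise was calibrated once, by simulation, so
  that Cronbach's alpha lands near 0.79 (unpredictability) and 0.77
  (harshness) and the two composites correlate near 0.37; the calibrated
  values are frozen in `cohort_config()`.
* **Influence link.** Each participant's true weight is
  $\delta = \mathrm{clip}(0.2 + 0.03 \cdot \mathrm{adversity} +
  \varepsilon,\ 0, 1)$ with $\varepsilon \sim N(0, 0.05)$; the slope 0.03
  per adversity unit is the pilot-scale effect the inference stage is
  expected to recover. A linear-with-clipping link (rather than logistic)
  matches the linear effect estimates the inference layer fits; the
  clipping bounds are part of the configuration. Internal noise
  $\sigma$ is drawn from $N(0.9, 0.2)$ truncated below at 0.05 — no
  per-participant noise distribution is documented for the original
  cohorts, so this is a calibration choice, not an empirical value.
* **Trials.** Initial ratings follow a discrete triangular distribution
  peaked at 4–5 (mid-scale-centred rating tendency; it keeps ±3 feedback
  almost always on-scale). Condition assignment is re-drawn (up to
  `clip_retry_cap`, default 200) until no feedback trial would clip, then
  clipped trials are accepted and flagged. Post-test ratings are drawn from
  the model pmf itself, with $\mu = x_\mathrm{ini}$ in agreement and
  no-feedback trials.
* **Determinism.** Every participant draws from a stream derived from the
  master seed, so cohorts are byte-identical across reruns and independent
  of participant order.

What the generator deliberately does *not* model: face-identity effects,
order or learning effects across the post-test, demographic effects on
$\delta$, or real questionnaire response styles (acquiescence, attention
lapses). Passing recovery tests on this cohort therefore demonstrates that
the estimation and inference machinery is correct and unbiased under the
assumed data-generating process — not that the model is true of human
raters.

## Inference and pooling

Because the environment predictors are between-participant and the design
is balanced, the condition-level mixed model with a random intercept per
participant has the same fixed-effect estimate as OLS on participant-level
means (the tests assert this against a brute-force GLS computation).
`env_regression()` therefore fits participant-level OLS of the overall
alignment score, or of $\hat\delta$, on an environment score, and reports
Cook's distances with the conventional 4/N cutoff. `slope_outlier_filter()`
removes observations exceeding the cutoff in *any* configured regression
(the union rule) and refits; it refuses to act when fewer than 3
observations would remain. Mixed-model machinery and Bayes-factor model
comparison are intentionally out of scope — the scored tables export
cleanly to any statistics package.

`meta_fixed()` implements inverse-variance fixed-effects pooling from its
closed forms: $w_i = 1/\mathrm{se}_i^2$, pooled effect
$\sum w_i \beta_i / \sum w_i$, pooled SE $(\sum w_i)^{-1/2}$, normal z test,
95% CI at ±1.96 SE, heterogeneity $Q = \sum w_i (\beta_i - \hat\beta)^2$ on
k − 1 df, and per-study contributions as normalized weights. The tests
cross-check every component against `metafor::rma(method = "FE")`. Two-sided
p-values come from the normal (pooling) and t (OLS) references, with no
multiple-testing correction.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations as
follows: likelihood normalization over 1,000 random $(\mu, \sigma)$;
likelihood-vs-oracle and optimizer-vs-grid comparisons over 20 simulated
participants each; parameter recovery over 500 participants with 18
feedback trials ($\delta \sim U(0,1)$, $\sigma \sim U(0.5, 1.5)$); and link
recovery over 60 cohorts of 500 participants (per-participant fits inside
that loop use a 3 × 3 start grid, which the oracle comparisons show is
already sufficient on 18-trial data). These sizes give Monte-Carlo error
comfortably below the tolerances being asserted.

## Known limitations

* The per-participant $\sigma$ distribution and the initial-rating
  distribution are calibration choices; conclusions about them should not
  be read off the generator.
* With 18 feedback trials, $\hat\delta$ is noisy (recovery r ≈ 0.8, not 1);
  cohort-level links are recovered unbiasedly, but individual estimates
  should be treated as such.
* The clipped-feedback convention (classify by nominal condition, optional
  drop) matters only for extreme initial ratings; with the default
  mid-scale rating distribution fewer than ~1% of trials are affected.
* `meta_fixed()` assumes a common true effect; it is a desk-scale pooling
  tool, not a replacement for a full random-effects analysis.
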