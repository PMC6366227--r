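# socialign

People differ in how much they fold other people's opinions into their own
judgements. `socialign` is an R package for studying that variability in a
standard two-phase face-evaluation task: participants rate 24 unfamiliar
faces on an 8-point approachability scale, then re-rate them after seeing a
(bogus) group rating that agrees with them, disagrees by ±2 or ±3 scale
points, or is absent. The package is aimed at behavioural and cognitive
scientists who want the full analysis chain — task design, scoring, choice
modelling, inference, meta-analytic pooling — as tested, reusable code, plus
a synthetic cohort generator with known ground truth so every stage can be
validated without collecting data.

## What it computes

**Behaviour.** Per condition, the mean rating change (post − test); the
*social alignment score* flips its sign in negative-disagreement conditions
so that positive values always mean movement towards the group.

**The choice model.** Post-test ratings are modelled as a discretized
normal around a compromise between own and group ratings,

```
mu   = x_ini * (1 - delta) + x_group * delta
p(x) = Phi(x + 1/2; mu, sigma) - Phi(x - 1/2; mu, sigma),  x in 1..8
```

with the out-of-scale tail mass absorbed at ratings 1 and 8. `delta` is the
social-influence weight (0 = ignore the group, 1 = adopt its rating),
`sigma` the internal noise in rating units. `fit_participant()` obtains
per-participant maximum-likelihood estimates by bounded multi-start
optimization, certified in the tests against an exhaustive grid search
(`fit_oracle_grid()`).

**Environment.** Childhood unpredictability (3 household-chaos items) and
harshness (3 reverse-coded perceived-wealth items) are averaged, z-scored,
and summed into an adversity composite; `cronbach_alpha()` and 1.5 × IQR
outlier screens cover the quality-check steps.

**Inference.** Participant-level OLS of alignment (or fitted delta) on
environment scores with Cook's-distance slope-outlier filtering at the 4/N
cutoff, and inverse-variance fixed-effects meta-analysis (`meta_fixed()`)
with heterogeneity Q and per-study contributions.

## Worked example

```r
library(socialign)
cfg <- run_config("synthetic", seed = 42,
                  cohort = cohort_config(n_participants = 120))
run <- run_pipeline(cfg, out_dir = "out")
```

The pipeline logs each stage with participant accounting:

```
simulate: 120 participants, 2880 trials (seed 42)
score: alignment and environment composites for 120 participants
score: Cronbach alpha unpredictability = 0.74, harshness = 0.76
exclude: 3 alignment outlier(s), 1 unpredictability outlier(s) (1.5 x IQR)
exclude: 116 of 120 participants retained (loss 3%)
fit: choice model fitted to 116 participants (116 converged)
predict: model-predicted alignment for 116 participants
infer: 8 slope outlier(s) by Cook's D > 4/N (union over regressions)
```

The generator plants a linear link from adversity to the influence weight
(slope 0.03 per adversity unit, around an intercept of 0.2); the inference
stage recovers it from the fitted parameters:

```r
print(run$inference$delta_on_adversity)
#> OLS delta ~ adversity (n = 116): beta = 0.0286 +/- 0.0066, t = 4.34, p = 3.11e-05
#>   1 observation(s) with Cook's D > 4/N = 0.0345
```

i.e. the estimated slope 0.029 ± 0.007 covers the planted 0.03. Pooling
per-study coefficients (here: the effect of childhood unpredictability on
alignment in two studies, entered as beta ± SE) gives a weighted average
with a text forest plot:

```r
meta_fixed(c(0.13, 0.037), c(0.05, 0.03), labels = c("pilot", "replication"))
#> Fixed-effects meta-analysis
#>   pilot          --------------|--======*======   0.130 [ 0.032,  0.228]  w = 26%
#>   replication    -------------=|==*====--------   0.037 [-0.022,  0.096]  w = 74%
#>   pooled         --------------|===*====-------   0.062 [ 0.011,  0.112]
#>   z = 2.40, p = 0.0166; Q = 2.54 (df 1, p = 0.111)
```

The pooled effect 0.062 ± 0.026 is significant (z = 2.40) even though the
larger study alone is not — the usual argument for pooling a pilot with its
replication. `run_pipeline()` writes all intermediate tables (trials,
scored participants, a synthetic-truth sidecar, fits, predictions,
inference coefficients) as tab-separated text with provenance headers, and
ingests the same formats in `mode = "real"`.

See `vignette("socialign-methods")` for the model's assumptions, the
generator's calibration, and the numerical design choices.

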