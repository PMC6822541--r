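---
title: "Models and methods: Bayesian analysis of blubber steroid hormones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: Bayesian analysis of blubber steroid hormones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blubberBayes)
```

This vignette is the package's own account of its statistical
machinery: the models, their assumptions and priors, the numerical
choices that matter, what the synthetic-data generators do and do not
emulate, and the known limitations.

## The scientific setting

Steroid hormones archived in whale blubber integrate weeks of endocrine
state, so a single dart biopsy can classify reproductive condition
without capture. Two hormones carry the signal of interest here:
progesterone in females, whose blubber concentrations split into a
low group (resting or lactating) and a high group (pregnant / luteal),
and testosterone in males, whose annual rise marks the breeding season.
Concentrations span orders of magnitude and are strictly positive, so
every model in the package works with a normal likelihood on
`log(concentration)`; location parameters are reported exponentiated, as
geometric means in ng g⁻¹.

## Assay quality control and validation

Enzyme-immunoassay measurements enter the analysis only after the QC
rules implemented in `duplicate_cv()` and `range_check()`:

* duplicate coefficient of variation `100 · sd/mean`; samples above 10%
  are flagged for rerun;
* the dilution-corrected mean must sit inside the assay working range
  of 50–3200 pg mL⁻¹. Both bounds are treated as inclusive — the
  permissive reading, affecting only exact-boundary values.
* the CV rule is applied to back-calculated concentrations (rather than
  raw optical densities), which is what plate exports usually contain.

Validation statistics mirror standard immunoassay practice.
`accuracy_test()` regresses measured hormone on the added standard mass
(Bayesian simple linear regression, vague `N(0, 100²)` coefficient
priors, `Half-Normal(0, 100)` residual scale): a slope far from 1
indicates matrix interference. `parallelism_test()` fits the standard
curve and a pooled-sample serial dilution as straight lines in
response-versus-log-concentration space and calls the curves parallel
when the 95% credible interval of the slope difference contains zero.
The linearized-response formulation replaces a by-eye judgement with an
explicit interval criterion; a logit-transformed binding response would
be an alternative, but the linear form needs no bound parameters and is
adequate over the central part of the curve where dilution series are
run. `recovery_efficiency()` reports the mean of per-spike percent
recoveries and their CV, the convention under which a single percentage
plus CV summarises a spike series. Cross-reactivity percentages quoted
by assay manufacturers are documentation; no computation uses them.

## The sampling engine

All posteriors are drawn by one generic component-wise adaptive
random-walk Metropolis sampler (`sample_posterior()`). Design choices:

* **Kernel.** Component-wise Gaussian proposals; per-coordinate scales
  adapt toward 0.44 acceptance by Robbins–Monro on the log scale,
  in 50-iteration batches, *only during burn-in*. The retained chain
  therefore comes from a fixed, valid kernel. A correct stationary
  distribution is the contract; the kernel itself is deliberately the
  simplest one that can be verified against closed-form posteriors
  (conjugate normal mean, Beta–Bernoulli) and a grid approximation for
  a tiny mixture — which the test suite does.
* **Bookkeeping.** A configuration of `n` iterations, burn-in fraction
  `b` and thinning `t` retains exactly `floor(n(1-b)/t)` draws per
  chain: burn-in is removed before thinning, and the effective burn-in
  is enlarged by the division remainder so the invariant holds for any
  configuration. The publication-scale configuration (3 chains ×
  1,000,000 iterations, 10% burn-in, thin 20; 135,000 retained draws)
  is available as `publication_chain_config()`; the default
  (3 × 20,000, thin 5) is sized for interactive use and CI.
* **Constrained parameters** are sampled on unconstrained scales
  (log SDs, logit weights) with the Jacobian in the log posterior;
  circular phases are folded back into `[0, 365)` after each proposal,
  which preserves proposal symmetry on the circle.
* **Diagnostics.** `gelman_rubin()` is the split-chain potential scale
  reduction factor (each chain halved; constant chains return 1 by
  convention). `effective_sample_size()` combines per-chain FFT
  autocovariances and truncates the autocorrelation sum by Geyer's
  initial monotone positive sequence; the result is capped at the
  retained count, so `Neff (%) ≤ 100` (antithetic chains would
  otherwise report more effective than actual draws).
* **Quantiles** in all summaries use the inverse-ECDF rule
  (`type = 1`). This makes quantiles commute exactly with monotone
  transforms — `quantile(exp(x), q) = exp(quantile(x, q))` — so a table
  reported on the concentration scale is exactly the exponentiated
  log-scale table. Interpolating rules (the R default, type 7) break
  this identity.
* The **SD column** of summary tables is the standard deviation of the
  *transformed* draws (on the reporting scale). The geometric spread
  `exp(sd(log draws))` is a different quantity; both can be computed
  from the samples, and the table documents which one it shows.

## The progesterone mixture model

`fit_mixture()` models log-concentrations as a two-component normal
mixture with weight `w_B` on the upper component. Defaults:
`m ~ N(0, 10²)`, `s ~ Half-Normal(0, 5)`, `w_B ~ Uniform(0, 1)` — all
overridable. Two components are fixed by design: the scientific
question is whether the observed bimodality is real and where the two
modes sit, not how many modes a nonparametric fit would find.

* **Identifiability.** The mixture likelihood is symmetric under label
  exchange. Labels are resolved per retained draw by relabelling so
  `m_A < m_B` (ordered means). Relabelling after sampling gives the
  same posterior as an ordered prior for every label-invariant
  quantity, and keeps the sampler free to move.
* **Latent indicators.** The sampled likelihood marginalizes the
  per-female cluster indicators; `z_i` draws are recovered afterwards
  from their exact conditional Bernoulli given each retained draw.
  This is distributionally identical to carrying `z` in the chain
  (no other conditional depends on `z`) and mixes better.
* **Cluster occurrence vs mixing weight.** `cluster_occurrence()`
  summarizes the *realized* fraction of sampled females per cluster
  (per-draw mean of the indicators). That interval is a predictive-type
  statement about the animals actually sampled; the posterior of the
  mixing weight `w_B` is the population-level parameter. They are close
  in the middle but have different calibration targets: in repeated
  sampling at a fixed generating weight, the weight's CI covers the
  generating weight at the nominal rate, while the occurrence CI covers
  each dataset's realized fraction. Both are exposed.
* `cluster_source_probability()` averages the conditional
  cluster-B probability of a concentration over the posterior — the
  curve that classifies new values. When the component SDs are equal it
  is monotone in the concentration.
* Lactating females are fitted together with unknown-stage females;
  the stage label is reporting metadata, not a model covariate. Repeat
  biopsies of the same whale enter as independent records — at the
  spacing of months between repeats, blubber concentrations are
  plausibly independent draws from the animal's current state, and the
  alternative (averaging) would discard state changes, which are
  exactly what repeat sightings document.

## The testosterone seasonal model

`fit_seasonal()` models log-testosterone as
`alpha + A·cos(2π(d − φ)/365) + ε`, `ε ~ N(0, sigma²)`, with
`alpha, A ~ N(0, 10²)`, `sigma ~ Half-Normal(0, 5)` and `φ` uniform on
the circle. The period is fixed at 365 days; leap days are ignored
(records keep their calendar day of year, a sub-resolution detail at
this noise level). A single harmonic is deliberate: with a few dozen
observations and a seasonal hypothesis, one cosine is the most
parsimonious shape whose amplitude, phase and explained variance map
directly onto the scientific claims.

* **Winter replication.** `augment_winter_replication()` duplicates
  records with day of year in a configurable winter window (default
  days 1–90, January–March) at `day + 365`, flagged `replicated`.
  Because the model is 365-periodic, this is exactly a doubling of the
  winter records' likelihood weight; it anchors both ends of the cycle
  when field effort leaves the late autumn unsampled. The default
  window is a calendar convention, not a fitted quantity, and the test
  suite asserts the replication-equals-reweighting equivalence.
* **Phase identifiability and the sign of the amplitude.** The pair
  `(A, φ)` and `(−A, φ + 182.5)` define the same curve. The sampler
  works on the full circle and every reported quantity is built from
  the label-invariant per-draw *peak day* (the day the draw's curve is
  maximal). The canonical signed amplitude is `|A|` signed by whether
  the draw's curve sits above its annual mean at a fixed
  `reference_day` — by default day 227 (mid-August), encoding the
  late-summer breeding hypothesis for this population; users studying
  other systems should set their own hypothesized season.
  `p_positive_amplitude` is the fraction of draws with positive
  canonical amplitude. Why a *fixed* reference rather than a
  data-driven one: the sign of any trend statistic judged against the
  posterior's own consensus phase is biased positive (about 0.77 on
  average under a flat cycle, independent of sample size, because the
  apparent noise phase and the posterior spread shrink together), and
  a free-sign `P(A > 0)` is exactly ½ for any data under a perfectly
  mixing sampler. Against a fixed reference the statistic is symmetric
  about ½ over replicate no-signal datasets and goes to 1 when a real
  peak lies in the reference half-cycle. For a single no-signal
  dataset the value still reflects the realized noise phase (it is
  close to uniform on (0, 1)); calibration checks under the null must
  therefore average over datasets, which the test suite does.
  The posterior consensus peak (circular mean of per-draw peak days),
  a circular-median peak-day estimate, and the fraction of draws
  agreeing with the consensus (`trend_coherence`) are reported
  alongside.
* **Bayesian R².** Per draw, `Var(fitted)/(Var(fitted) + sigma²)` with
  the fitted-value variance taken over the observed days (population
  formula). Bounded in [0, 1]; 0 for a flat draw, 1 in the noiseless
  limit; summarized with mean and 95% CI.
* **Bands.** `predict_band()` reports, per grid day, inverse-ECDF
  posterior quantiles of the geometric-mean curve
  `exp(alpha + A·cos(·))` — nested 75% and 95% credible bands of the
  *mean* curve by default. Observation-level posterior-predictive bands
  (one log-normal draw per posterior draw, seeded from the fit's
  configuration) are available via `type = "predictive"`; the default
  matches how a mean seasonal trend with credible shading is usually
  drawn.

## Synthetic data: what it does and does not emulate

The generators invert the three models at parameter values typical of
published fin whale blubber measurements: a progesterone mixture with
geometric means near 1.56 and 27.12 ng g⁻¹ and low-cluster weight
0.61; seasonal testosterone peaking in late August; spike-recovery
series with slope near 0.83. Within-cluster log-SDs (0.55, 0.85) are
plausibility choices — published summaries report posterior SDs of the
cluster *means*, not within-cluster spreads — set so the clusters
overlap only in their tails, and the default seasonal amplitude
(1.0 log-unit) likewise stands in for an unpublished quantity. Sampling
days are uniform over a configurable window (default days 30–300) to
mimic uneven field effort with little winter/late-autumn coverage.
Every generator is a pure function of its parameters and seed and emits
the same CSV dialect the readers parse.

What the generators do *not* emulate: inter-individual variability
(repeat biopsies of one male are not correlated), year effects, plate
optical densities and four-parameter standard curves, and any spatial
structure. Passing recovery tests therefore demonstrates that the
inference machinery recovers the generating process of these models —
not that real biopsy data satisfy the models' assumptions.

## Problem sizes and numerical choices

The test suite runs recovery fits at n = 84–300 observations with
3 × 20,000-iteration chains (thin 5) for headline checks and
2 × 3,000-iteration chains for 40–50-replicate calibration loops; these
sizes give Monte-Carlo errors comfortably inside the asserted
tolerances while keeping a full run in a few minutes. Degenerate inputs
are rejected up front (all-identical concentrations, all-equal
regression abscissae, single-day seasonal designs, nonpositive
concentrations); noiseless inputs are legal and drive the residual
scale toward zero without numerical failure (proposals that underflow
the likelihood are simply rejected). Initial values are data-driven
(quantiles for the mixture, a least-squares harmonic fit for the
seasonal model) and deliberately over-dispersed across chains so the
split-R̂ diagnostic is informative.

## Known limitations

* No individual random effects: repeat biopsies are treated as
  independent, understating uncertainty if one animal contributes many
  records.
* The seasonal shape is a single fixed-period harmonic; multimodal or
  asymmetric cycles would be mis-summarized.
* Component count of the mixture is fixed at two; the package reports
  clusters, it does not test "2 vs 3".
* The assay module consumes back-calculated concentrations; it does not
  fit standard curves or model inter-plate drift.
* `p_positive_amplitude` for a single dataset without true seasonality
  is not a calibrated p-value — it is a posterior statement conditional
  on that dataset's noise phase (see above).
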