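# blubberBayes

Bayesian inference of reproductive state and breeding seasonality in
baleen whales from steroid hormone concentrations measured in blubber
biopsies.

Blubber is a practical matrix for endocrine monitoring of free-ranging
whales: a small dart biopsy yields enough tissue to quantify lipophilic
steroids by enzyme immunoassay (EIA). Two questions drive the analysis
this package implements for a population of fin whales:

1. **Which females are reproductively active?** Blubber progesterone in
   females is strongly bimodal on the log scale — a low-concentration
   group (resting/lactating) and a high-concentration group (likely
   pregnant or in the luteal phase).
2. **When do males breed?** Blubber testosterone in males rises toward
   the mating season, so its seasonal cycle dates the breeding period.

## Models

All concentrations `y` (ng g⁻¹ blubber) are modelled on the natural-log
scale.

**Two-component normal mixture** (female progesterone):

```
log y_i ~ (1 - w_B) N(m_A, s_A²) + w_B N(m_B, s_B²),   m_A < m_B
```

with priors `m ~ N(0, 10²)`, `s ~ Half-Normal(0, 5)`, `w_B ~ U(0, 1)`.
Reported quantities: geometric cluster means `exp(m_A)`, `exp(m_B)`; the
posterior probability that a given concentration arose from each
cluster; and the posterior distribution of cluster occurrence (the
fraction of sampled females in each cluster, via per-draw latent
indicator draws `z_i`).

**Log-normal location model** (male testosterone):
`log y_i ~ N(mu, sigma²)`, reported as the geometric mean `exp(mu)`.

**Sinusoidal day-of-year model** (male testosterone seasonality):

```
log y_i ~ N(alpha + A cos(2π (d_i - φ) / 365), sigma²)
```

where `d_i` is the day of year and `φ` the peak day. Because field
effort leaves parts of the cycle unsampled, winter observations are
replicated as the first part of a hypothetical second year
(`augment_winter_replication()`), which anchors both ends of the fitted
cycle (the model is 365-periodic, so this equals doubling their
likelihood weight). The fit reports the posterior peak day, the
probability of positive amplitude at a fixed reference day (default
mid-August, day 227), Bayesian R² (per-draw fitted-variance /
fitted-plus-residual-variance), and 75%/95% posterior bands of the mean
seasonal curve.

Inference uses a built-in adaptive random-walk Metropolis sampler
(adaptation confined to burn-in) with split-chain Gelman–Rubin R̂ and
autocorrelation-based effective sample size; summaries use the layout
`Mean, SD, 2.5%, 25.0%, 50.0%, 75.0%, 97.5%, Rhat, Neff (%)`.

The package also implements EIA quality control and validation:
duplicate CV with the >10% rerun rule, the 50–3200 pg mL⁻¹ working-range
check, spike-recovery efficiency, and Bayesian accuracy (slope of
measured on added mass) and parallelism (slope-difference CI of standard
vs serial-dilution curves) tests. Seeded synthetic-data generators
(`gen_mixture_concentrations()`, `gen_seasonal_concentrations()`,
`gen_assay_series()`) produce datasets with the same statistical
structure so the entire pipeline is testable end to end.

## Worked example

```r
library(blubberBayes)

# assay QC: duplicate wells 612 and 688 pg/mL
qc <- duplicate_cv(assay_measurement("P07", c(612, 688)))
#> CV 8.27%, rerun: FALSE, in_range

# simulate 34 female progesterone biopsies and fit the mixture
g   <- gen_mixture_concentrations(mixture_sim_params(n = 34, seed = 1))
fit <- fit_mixture(g$dataset$concentration, chain_config(seed = 1))
summarize_mixture(fit)
#>     parameter  Mean    SD  2.5% 25.0% 50.0% 75.0% 97.5% Rhat Neff (%)
#> 1 mu_ClusterA  1.93 0.219  1.54  1.78  1.91  2.05   2.4    1     69.0
#> 2 mu_ClusterB 26.61 6.674 11.63 22.88 26.89 30.62  39.6    1     37.2

cluster_occurrence(fit)$fraction_A
#> 0.64   (95% CI 0.50-0.68)
cluster_source_probability(fit, c(0.76, 18.26, 173.36))
#> 0.031 0.997 0.998      # P(cluster B | concentration)
```

The cluster means are geometric means in ng g⁻¹: here the low cluster
sits near 1.9 ng g⁻¹ and the high cluster near 27 ng g⁻¹, about 64% of
the sampled females belong to the low cluster, and a female at
173 ng g⁻¹ is essentially certainly in the high (reproductively active)
cluster.

```r
# simulate 44 male testosterone biopsies and fit the seasonal model
g   <- gen_seasonal_concentrations(seasonal_sim_params(n = 44, seed = 2))
fit <- fit_seasonal(augment_winter_replication(g), chain_config(seed = 2))
fit
#> seasonal_fit: n = 54, 10800 retained draws
#>   P(positive amplitude at reference day 227) = 1.000
#>   posterior median peak day = 221.1 (consensus 221.2)
bayesian_r2(fit)$mean
#> 0.69   (95% CI 0.55-0.79)
attr(predict_band(fit), "peak_day")
#> 221
```

The testosterone cycle peaks in mid/late August (day ~221) with
complete posterior certainty of a seasonal trend — the signature of a
late-summer mating season.

`run_full_analysis()` orchestrates the full pipeline (CSV in → QC →
all three fits → summary/band/probability-curve CSVs plus a JSON run
manifest), and `simulate_fixtures()` materializes canonical synthetic
datasets; both are deterministic given one global seed.

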