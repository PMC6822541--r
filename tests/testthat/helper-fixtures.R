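# Shared fixtures: chain configurations scaled for the test suite, tiny
# datasets built in code, and a degenerate point-mass mixture fit used to
# check probability formulas against hand computations.

# full test-scale configuration (3 x 20,000, 10% burn-in, thin 5)
cfg_test <- function(seed = 1L) chain_config(3L, 20000L, 0.1, 5L, seed)

# light configuration for loops over many fits
cfg_light <- function(seed = 1L) chain_config(2L, 3000L, 0.1, 3L, seed)

# minimal configuration for cheap sampler checks
cfg_mini <- function(seed = 1L) chain_config(2L, 2000L, 0.1, 1L, seed)

tiny_dataset <- function() {
  hormone_dataset(
    whale_id = c("C001", "C002", "C003", "C101"),
    sex = c("female", "female", "female", "male"),
    hormone = c("progesterone", "progesterone", "progesterone",
                "testosterone"),
    concentration = c(1.2, 27.5, 173.36, 0.9),
    date = c("2015-02-10", "2016-07-03", "2015-08-12", "2017-09-17"),
    provenance = "test fixture")
}

# mixture_fit whose posterior is a single point mass at the given
# parameter values (1 chain, 1 retained draw); enough structure for
# cluster_source_probability()
point_mass_mixture_fit <- function(m_A, m_B, s_A, s_B, w_B) {
  cfg <- chain_config(1L, 1L, 0, 1L, seed = 1L)
  draw <- matrix(c(m_A, m_B, s_A, s_B, w_B), nrow = 1,
                 dimnames = list(NULL, c("m_A", "m_B", "s_A", "s_B", "w_B")))
  samples <- blubberBayes:::new_posterior_samples(list(draw), cfg)
  structure(list(samples = samples, z = matrix(FALSE, 1, 1),
                 log_concentrations = 0, n = 1, config = cfg),
            class = "mixture_fit")
}

# least-squares harmonic regression oracle: peak day of a 365-period
# cosine fitted to (day, log concentration)
ls_harmonic_peak <- function(day, log_conc) {
  cx <- cos(2 * pi * day / 365)
  sx <- sin(2 * pi * day / 365)
  co <- stats::coef(stats::lm(log_conc ~ cx + sx))
  (atan2(co[3], co[2]) * 365 / (2 * pi)) %% 365
}
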