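# Seeded generators producing datasets with the statistical structure the
# analysis assumes: a two-component log-normal mixture for female
# progesterone, a sinusoidal seasonal log-normal for male testosterone, and
# linear spike-recovery / parallelism series for assay validation. Every
# generator is a pure function of (params, seed): identical inputs yield
# byte-identical output, and the caller's RNG state is left untouched.

#' Simulation parameters for the progesterone mixture generator
#'
#' @param n number of simulated females (>= 1).
#' @param weight_A probability of the low-concentration cluster A,
#'   strictly in (0, 1).
#' @param geo_mean_A,geo_mean_B geometric means (ng per g) of the two
#'   clusters; must satisfy `geo_mean_A < geo_mean_B` (canonical labelling).
#' @param log_sd_A,log_sd_B within-cluster SDs on the natural-log scale
#'   (> 0). Defaults give cluster overlap confined to the tails, as seen in
#'   blubber progesterone.
#' @param seed integer RNG seed.
#' @return A `mixture_sim_params` list.
#' @export
mixture_sim_params <- function(n = 34L, weight_A = 0.61,
                               geo_mean_A = 1.56, geo_mean_B = 27.12,
                               log_sd_A = 0.55, log_sd_B = 0.85,
                               seed = 1L) {
  stopifnot(n >= 1, weight_A > 0, weight_A < 1,
            geo_mean_A > 0, geo_mean_B > 0)
  if (!(geo_mean_A < geo_mean_B))
    stop("geo_mean_A must be < geo_mean_B (canonical labelling)",
         call. = FALSE)
  if (!(log_sd_A > 0) || !(log_sd_B > 0))
    stop("log-scale SDs must be strictly positive", call. = FALSE)
  structure(list(n = as.integer(n), weight_A = weight_A,
                 geo_mean_A = geo_mean_A, geo_mean_B = geo_mean_B,
                 log_sd_A = log_sd_A, log_sd_B = log_sd_B,
                 seed = as.integer(seed)),
            class = "mixture_sim_params")
}

#' Simulation parameters for the seasonal testosterone generator
#'
#' Log-concentration of male testosterone follows
#' `alpha + amplitude * cos(2*pi*(day - peak_day)/365) + N(0, sigma)`.
#'
#' @param n number of simulated males.
#' @param alpha intercept, log ng per g.
#' @param amplitude seasonal amplitude, log-units.
#' @param peak_day day of year of the seasonal peak, in `[1, 365]`.
#' @param sigma residual SD, log-units (> 0).
#' @param day_range integer interval (length 2) within `[1, 365]` from
#'   which sampling days are drawn uniformly; a restricted window mimics
#'   uneven field effort across the year.
#' @param seed integer RNG seed.
#' @return A `seasonal_sim_params` list.
#' @export
seasonal_sim_params <- function(n = 44L, alpha = 0, amplitude = 1.0,
                                peak_day = 227, sigma = 0.7,
                                day_range = c(30L, 300L), seed = 1L) {
  stopifnot(n >= 1, is.finite(alpha), is.finite(amplitude),
            peak_day >= 1, peak_day <= 365, sigma > 0)
  day_range <- as.integer(round(day_range))
  if (length(day_range) != 2L || day_range[1] > day_range[2] ||
      day_range[1] < 1L || day_range[2] > 365L)
    stop("day_range must be a nonempty integer interval within [1, 365]",
         call. = FALSE)
  structure(list(n = as.integer(n), alpha = alpha, amplitude = amplitude,
                 peak_day = peak_day, sigma = sigma, day_range = day_range,
                 seed = as.integer(seed)),
            class = "seasonal_sim_params")
}

#' Simulation parameters for assay validation series
#'
#' @param true_slope slope of measured on added mass (1 = perfectly
#'   accurate assay).
#' @param intercept intercept of the spike-recovery line.
#' @param noise_sd SD of measurement noise (>= 0; 0 gives exact lines).
#' @param added_masses strictly increasing positive spike masses.
#' @param dilution_steps number of 2-fold serial dilution points.
#' @param parallel_slope_ratio ratio of the pooled-sample dilution-curve
#'   slope to the standard-curve slope (1 = parallel).
#' @param seed integer RNG seed.
#' @return An `assay_sim_params` list.
#' @export
assay_sim_params <- function(true_slope = 0.83, intercept = 0,
                             noise_sd = 0,
                             added_masses = c(50, 100, 200, 400, 800, 1600),
                             dilution_steps = 6L,
                             parallel_slope_ratio = 1,
                             seed = 1L) {
  stopifnot(is.finite(true_slope), is.finite(intercept), noise_sd >= 0,
            dilution_steps >= 3L, parallel_slope_ratio > 0)
  if (any(added_masses <= 0) || any(diff(added_masses) <= 0))
    stop("added_masses must be strictly increasing and positive",
         call. = FALSE)
  structure(list(true_slope = true_slope, intercept = intercept,
                 noise_sd = noise_sd, added_masses = added_masses,
                 dilution_steps = as.integer(dilution_steps),
                 parallel_slope_ratio = parallel_slope_ratio,
                 seed = as.integer(seed)),
            class = "assay_sim_params")
}

# deterministic pseudo-dates for simulated records: day_of_year d in a
# fixed non-leap reference year
sim_date <- function(day) as.Date(day - 1L, origin = "2015-01-01")

#' Generate bimodal log-normal progesterone concentrations
#'
#' Inverts the two-component mixture model: each female's cluster is drawn
#' Bernoulli (cluster B with probability `1 - weight_A`) and her
#' concentration is log-normal around that cluster's geometric mean. The
#' generating labels are returned for parameter-recovery tests.
#'
#' @param params a [mixture_sim_params()].
#' @return List with `dataset` (a `hormone_dataset` of female progesterone
#'   records) and `true_labels` (character, "A"/"B").
#' @export
gen_mixture_concentrations <- function(params) {
  stopifnot(inherits(params, "mixture_sim_params"))
  with_seed(params$seed, {
    z <- stats::rbinom(params$n, 1L, 1 - params$weight_A)  # 1 = cluster B
    mu <- ifelse(z == 1L, log(params$geo_mean_B), log(params$geo_mean_A))
    sdv <- ifelse(z == 1L, params$log_sd_B, params$log_sd_A)
    conc <- exp(stats::rnorm(params$n, mu, sdv))
    days <- sample.int(365L, params$n, replace = TRUE)
    ds <- hormone_dataset(
      whale_id = sprintf("SIMF%03d", seq_len(params$n)),
      sex = "female", hormone = "progesterone",
      concentration = conc, date = sim_date(days),
      provenance = sprintf("gen_mixture_concentrations(seed=%d)", params$seed))
    list(dataset = ds, true_labels = ifelse(z == 1L, "B", "A"))
  })
}

#' Generate seasonally varying testosterone concentrations
#'
#' Inverts the sinusoidal day-of-year model: sampling days are uniform on
#' `day_range` and log-concentrations are
#' `alpha + amplitude * cos(2*pi*(day - peak_day)/365) + N(0, sigma)`.
#'
#' @param params a [seasonal_sim_params()].
#' @return A `hormone_dataset` of male testosterone records.
#' @export
gen_seasonal_concentrations <- function(params) {
  stopifnot(inherits(params, "seasonal_sim_params"))
  with_seed(params$seed, {
    days <- params$day_range[1] +
      sample.int(params$day_range[2] - params$day_range[1] + 1L,
                 params$n, replace = TRUE) - 1L
    mu <- params$alpha +
      params$amplitude * cos(2 * pi * (days - params$peak_day) / 365)
    conc <- exp(stats::rnorm(params$n, mu, params$sigma))
    hormone_dataset(
      whale_id = sprintf("SIMM%03d", seq_len(params$n)),
      sex = "male", hormone = "testosterone",
      concentration = conc, date = sim_date(days),
      provenance = sprintf("gen_seasonal_concentrations(seed=%d)", params$seed))
  })
}

#' Generate assay validation series
#'
#' Produces a spike-recovery (accuracy) series and a parallelism pair of
#' curves. The accuracy series is
#' `measured = intercept + true_slope * added + N(0, noise_sd)`. The
#' parallelism pair is a standard curve and a pooled-sample 2-fold serial
#' dilution, both linear in response vs log-concentration, the dilution
#' slope scaled by `parallel_slope_ratio` (1 means parallel).
#'
#' @param params an [assay_sim_params()].
#' @return List with data.frames `accuracy` (`added`, `measured`),
#'   `standard_curve` and `dilution_series` (`log_dose`, `response`).
#' @export
gen_assay_series <- function(params) {
  stopifnot(inherits(params, "assay_sim_params"))
  with_seed(params$seed, {
    added <- params$added_masses
    measured <- params$intercept + params$true_slope * added +
      stats::rnorm(length(added), 0, params$noise_sd)
    # standard curve: competitive-assay-like declining linear response on
    # log dose, spanning the allowed assay range
    log_dose <- seq(log(50), log(3200), length.out = params$dilution_steps)
    std_slope <- -20
    standard <- 100 + std_slope * (log_dose - log_dose[1]) +
      stats::rnorm(params$dilution_steps, 0, params$noise_sd)
    log_dil <- log(3200) - log(2) * (seq_len(params$dilution_steps) - 1L)
    dil_resp <- 100 + std_slope * params$parallel_slope_ratio *
      (log_dil - log_dose[1]) +
      stats::rnorm(params$dilution_steps, 0, params$noise_sd)
    list(
      accuracy = data.frame(added = added, measured = measured),
      standard_curve = data.frame(log_dose = log_dose, response = standard),
      dilution_series = data.frame(log_dose = log_dil, response = dil_resp)
    )
  })
}
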