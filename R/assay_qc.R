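# Enzyme-immunoassay quality control and validation statistics: duplicate
# coefficient of variation with the >10% rerun rule, the 50-3200 pg/mL
# working-range check, spike recovery, and Bayesian accuracy and
# parallelism tests.

ASSAY_RANGE_PG_ML <- c(50, 3200)

#' Duplicate coefficient of variation and rerun flag
#'
#' CV (%) of a sample's replicate back-calculated concentrations:
#' `100 * sd / mean`. Samples with CV above 10% are flagged for rerun. The
#' mean replicate value times the dilution factor is also checked against
#' the assay working range of 50-3200 pg/mL (bounds inclusive).
#'
#' @param measurement an [assay_measurement()].
#' @return A `qc_result` list: `sample_id`, `cv_percent`, `rerun_flag`,
#'   `range_status` ("in_range"/"below_range"/"above_range"), and
#'   `mean_concentration` (pg/mL, dilution-corrected).
#' @export
duplicate_cv <- function(measurement) {
  stopifnot(inherits(measurement, "assay_measurement"))
  v <- measurement$replicate_values
  if (all(v == 0))
    stop("CV undefined: all replicate values are zero", call. = FALSE)
  m <- mean(v)
  cv <- 100 * stats::sd(v) / m
  conc <- m * measurement$dilution_factor
  structure(list(sample_id = measurement$sample_id,
                 cv_percent = cv,
                 rerun_flag = cv > 10,
                 range_status = range_check(conc),
                 mean_concentration = conc),
            class = "qc_result")
}

#' Assay working-range check
#'
#' Classifies a back-calculated concentration against the assay's allowed
#' range of 50-3200 pg/mL; samples outside it are rerun at a different
#' dilution. Bounds are inclusive.
#'
#' @param concentration_pg_ml nonnegative concentration, pg per mL.
#' @return "below_range", "in_range" or "above_range" (vectorized).
#' @export
range_check <- function(concentration_pg_ml) {
  if (any(!is.finite(concentration_pg_ml) | concentration_pg_ml < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  out <- rep("in_range", length(concentration_pg_ml))
  out[concentration_pg_ml < ASSAY_RANGE_PG_ML[1]] <- "below_range"
  out[concentration_pg_ml > ASSAY_RANGE_PG_ML[2]] <- "above_range"
  out
}

#' Spike-recovery efficiency
#'
#' Per-spike recovery is `100 * measured / expected`; the reported
#' efficiency is the mean of the per-spike recoveries and its CV is
#' `100 * sd / mean` across spikes.
#'
#' @param measured numeric measured concentrations.
#' @param expected numeric expected (added) concentrations, > 0, same
#'   length as `measured`.
#' @return List with `recovery_percent`, `recovery_cv_percent` (`NA` for a
#'   single spike) and the vector `per_spike_percent`.
#' @export
recovery_efficiency <- function(measured, expected) {
  if (length(measured) != length(expected))
    stop("measured and expected must have the same length", call. = FALSE)
  if (length(measured) < 1L) stop("need at least one spike", call. = FALSE)
  if (any(expected <= 0)) stop("expected values must be > 0", call. = FALSE)
  rec <- 100 * measured / expected
  list(recovery_percent = mean(rec),
       recovery_cv_percent = if (length(rec) > 1L)
         100 * stats::sd(rec) / mean(rec) else NA_real_,
       per_spike_percent = rec)
}

# Bayesian simple linear regression y ~ a + b x with vague priors
# a, b ~ N(0, coef_sd^2), sigma ~ Half-Normal(0, sigma_sd); returns
# posterior_samples over (intercept, slope, log_sigma).
bayes_linreg <- function(x, y, config, coef_sd = 100, sigma_sd = 100) {
  lp <- function(th) {
    sigma <- exp(th[3])
    sum(stats::dnorm(y, th[1] + th[2] * x, sigma, log = TRUE)) +
      stats::dnorm(th[1], 0, coef_sd, log = TRUE) +
      stats::dnorm(th[2], 0, coef_sd, log = TRUE) +
      stats::dnorm(sigma, 0, sigma_sd, log = TRUE) + th[3]  # half-normal + Jacobian
  }
  ls_fit <- stats::lm.fit(cbind(1, x), y)
  r_sd <- stats::sd(ls_fit$residuals)
  if (!is.finite(r_sd) || r_sd < 1e-6 * max(stats::sd(y), 1)) {
    r_sd <- max(1e-6 * max(stats::sd(y), 1), 1e-9)
  }
  init0 <- c(ls_fit$coefficients[1], ls_fit$coefficients[2], log(r_sd))
  inits <- lapply(seq_len(config$n_chains), function(c)
    init0 + (c - 1) * c(0.1, 0.01, 0.1))
  sample_posterior(lp, inits, config,
                   param_names = c("intercept", "slope", "log_sigma"),
                   scale0 = c(max(r_sd, 1e-3), max(r_sd / stats::sd(x), 1e-4), 0.3))
}

#' Bayesian accuracy (spike-recovery regression) test
#'
#' Linear regression of measured hormone on the added standard mass, fitted
#' with a normal likelihood and vague priors. A slope much higher or lower
#' than 1 indicates over- or under-estimation (matrix interference);
#' Bayesian R-squared is reported as a per-draw ratio of fitted-value
#' variance to fitted-plus-residual variance.
#'
#' @param added numeric added masses (>= 3 distinct values).
#' @param measured numeric measured concentrations, same length.
#' @param config a [chain_config()].
#' @return A `validation_result` list: posterior median `slope` with
#'   `slope_ci95`, `intercept`, `br2` with `br2_ci95`, an `interpretation`
#'   string, and the underlying `samples`.
#' @export
accuracy_test <- function(added, measured, config = chain_config()) {
  if (length(added) != length(measured))
    stop("added and measured must have the same length", call. = FALSE)
  if (length(added) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(added) == 0)
    stop("added values are all equal; regression is degenerate",
         call. = FALSE)
  s <- bayes_linreg(added, measured, config)
  slope <- posterior_draws(s, "slope")
  sigma <- exp(posterior_draws(s, "log_sigma"))
  fitted_var <- slope^2 * stats::var(added) * (length(added) - 1) / length(added)
  br2 <- fitted_var / (fitted_var + sigma^2)
  slope_ci <- stats::quantile(slope, c(0.025, 0.975), type = 1, names = FALSE)
  med_slope <- stats::median(slope)
  interp <- if (slope_ci[1] > 1) "overestimation (slope above 1)"
  else if (slope_ci[2] < 1) "underestimation (slope below 1)"
  else "accurate (95% CI of slope includes 1)"
  structure(list(slope = med_slope, slope_ci95 = slope_ci,
                 intercept = stats::median(posterior_draws(s, "intercept")),
                 br2 = mean(br2),
                 br2_ci95 = stats::quantile(br2, c(0.025, 0.975), type = 1,
                                            names = FALSE),
                 interpretation = interp, samples = s),
            class = "validation_result")
}

#' Bayesian parallelism test
#'
#' Fits the assay standard curve and a pooled-sample serial-dilution curve
#' as straight lines in response vs log-concentration space and compares
#' their slopes. The curves are judged parallel when the 95% credible
#' interval of the slope difference contains 0 — evidence that the assay
#' measures the same antigen in standards and extracts.
#'
#' @param standard_curve data.frame with columns `log_dose`, `response`
#'   (>= 3 points).
#' @param dilution_series data.frame with columns `log_dose`, `response`
#'   (>= 3 points).
#' @param config a [chain_config()].
#' @return List with `parallel` (logical), `slope_difference` (posterior
#'   median), `slope_difference_ci95`, and the two slope posteriors.
#' @export
parallelism_test <- function(standard_curve, dilution_series,
                             config = chain_config()) {
  for (cur in list(standard_curve, dilution_series)) {
    if (!all(c("log_dose", "response") %in% names(cur)))
      stop("curves need columns 'log_dose' and 'response'", call. = FALSE)
    if (nrow(cur) < 3L)
      stop("need at least 3 points per curve", call. = FALSE)
  }
  s1 <- bayes_linreg(standard_curve$log_dose, standard_curve$response, config)
  cfg2 <- config
  cfg2$seed <- split_seed(config$seed, "parallelism-dilution")
  s2 <- bayes_linreg(dilution_series$log_dose, dilution_series$response, cfg2)
  d <- posterior_draws(s2, "slope") - posterior_draws(s1, "slope")
  ci <- stats::quantile(d, c(0.025, 0.975), type = 1, names = FALSE)
  list(parallel = ci[1] <= 0 && ci[2] >= 0,
       slope_difference = stats::median(d),
       slope_difference_ci95 = ci,
       standard_slope = stats::median(posterior_draws(s1, "slope")),
       dilution_slope = stats::median(posterior_draws(s2, "slope")))
}

#' Per-sample QC table
#'
#' Applies [duplicate_cv()] to a list of measurements and returns one row
#' per sample.
#'
#' @param measurements list of [assay_measurement()] objects.
#' @return data.frame with columns `sample_id`, `cv_percent`, `rerun_flag`,
#'   `range_status`, `mean_concentration`.
#' @export
qc_table <- function(measurements) {
  rows <- lapply(measurements, function(m) {
    r <- duplicate_cv(m)
    data.frame(sample_id = r$sample_id, cv_percent = r$cv_percent,
               rerun_flag = r$rerun_flag, range_status = r$range_status,
               mean_concentration = r$mean_concentration,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
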