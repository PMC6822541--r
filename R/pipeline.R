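# End-to-end orchestration: read data -> QC -> fit models -> emit
# posterior-summary / probability-curve / prediction-band CSVs plus a
# machine-readable run manifest. Also the fixture entry point that
# materializes canonical synthetic datasets.

#' Run the full hormone analysis pipeline
#'
#' Reads a hormone CSV, optionally computes assay QC/validation results,
#' fits the progesterone mixture model (females), the testosterone
#' log-normal location model (males), and the seasonal sinusoidal model on
#' winter-replication-augmented testosterone records, and writes all
#' outputs plus a JSON manifest to `outdir`. Deterministic given `seed`:
#' the global seed fans out to per-stage seeds via [split_seed()].
#'
#' @param input path to a hormone record CSV (see [read_hormone_csv()]).
#' @param outdir output directory (created if missing).
#' @param seed integer global seed.
#' @param config a [chain_config()]; its seed is overridden per stage.
#' @param winter_window day-of-year interval replicated into the second
#'   year (default `c(1, 90)`).
#' @param plate_csv optional path to an assay plate CSV with columns
#'   `sample_id`, `replicate_1`, `replicate_2`, ..., `dilution_factor`.
#' @param accuracy_csv optional path to a validation CSV with columns
#'   `added`, `measured`.
#' @param priors optional prior overrides passed to the model fits.
#' @return Invisibly, a list bundle: `data`, `qc`, `validation`,
#'   `mixture` (fit, summary, occurrence, probability curve), `location`,
#'   `seasonal` (fit, summary, Bayesian R2, band), and `manifest`.
#' @export
run_full_analysis <- function(input, outdir, seed = 1L,
                              config = chain_config(),
                              winter_window = c(1L, 90L),
                              plate_csv = NULL, accuracy_csv = NULL,
                              priors = NULL) {
  for (p in c(input, plate_csv, accuracy_csv))
    if (!is.null(p) && !file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  data <- read_hormone_csv(input)
  bundle <- list(data = data)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))
  stage_cfg <- function(stage) {
    cfg <- config
    cfg$seed <- split_seed(seed, stage)
    cfg
  }
  warn_rhat <- function(summary_tab, stage) {
    bad <- summary_tab$Rhat[!is.na(summary_tab$Rhat)] > 1.01
    if (any(bad))
      warning(sprintf("%s: Rhat > 1.01 for %s — inspect convergence", stage,
                      paste(summary_tab$parameter[bad], collapse = ", ")))
  }

  if (!is.null(plate_csv)) {
    plate <- utils::read.csv(plate_csv, stringsAsFactors = FALSE)
    rep_cols <- grep("^replicate_", names(plate), value = TRUE)
    if (!length(rep_cols))
      stop("plate CSV needs replicate_1..k columns", call. = FALSE)
    meas <- lapply(seq_len(nrow(plate)), function(i)
      assay_measurement(plate$sample_id[i],
                        unlist(plate[i, rep_cols], use.names = FALSE),
                        plate$dilution_factor[i] %||% 1))
    bundle$qc <- qc_table(meas)
    utils::write.csv(bundle$qc, file.path(outdir, "qc.csv"),
                     row.names = FALSE)
    log_stage("qc", sprintf("%d samples, %d flagged for rerun",
                            nrow(bundle$qc), sum(bundle$qc$rerun_flag)))
  }

  if (!is.null(accuracy_csv)) {
    acc <- utils::read.csv(accuracy_csv, stringsAsFactors = FALSE)
    bundle$validation <- accuracy_test(acc$added, acc$measured,
                                       stage_cfg("accuracy"))
    val <- bundle$validation
    utils::write.csv(
      data.frame(slope = val$slope, slope_lo95 = val$slope_ci95[1],
                 slope_hi95 = val$slope_ci95[2], intercept = val$intercept,
                 br2 = val$br2, br2_lo95 = val$br2_ci95[1],
                 br2_hi95 = val$br2_ci95[2],
                 interpretation = val$interpretation),
      file.path(outdir, "validation.csv"), row.names = FALSE)
    log_stage("validate", sprintf("slope %.3f [%.3f, %.3f]", val$slope,
                                  val$slope_ci95[1], val$slope_ci95[2]))
  }

  prog <- data[data$hormone == "progesterone" & !data$replicated, ]
  if (nrow(prog) >= 4L) {
    fit <- fit_mixture(prog$concentration, stage_cfg("mixture"),
                       priors = priors)
    tab <- summarize_mixture(fit)
    warn_rhat(tab, "cluster")
    occ <- cluster_occurrence(fit)
    vgrid <- exp(seq(log(min(prog$concentration)),
                     log(max(prog$concentration)), length.out = 200))
    pB <- cluster_source_probability(fit, vgrid)
    curve <- data.frame(concentration = vgrid, p_cluster_A = 1 - pB,
                        p_cluster_B = pB)
    write_summary_table(tab, file.path(outdir, "mixture_summary.csv"))
    utils::write.csv(curve, file.path(outdir, "cluster_probability_curve.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(cluster = c("A", "B"),
                 fraction = c(occ$fraction_A, occ$fraction_B),
                 lo95 = c(occ$fraction_A_ci95[1], occ$fraction_B_ci95[1]),
                 hi95 = c(occ$fraction_A_ci95[2], occ$fraction_B_ci95[2])),
      file.path(outdir, "cluster_occurrence.csv"), row.names = FALSE)
    bundle$mixture <- list(fit = fit, summary = tab, occurrence = occ,
                           probability_curve = curve)
    log_stage("cluster", sprintf("n = %d, occurrence A = %.2f", nrow(prog),
                                 occ$fraction_A))
  }

  test_rec <- data[data$hormone == "testosterone" & !data$replicated, ]
  if (nrow(test_rec) >= 2L) {
    loc <- fit_lognormal_mean(test_rec$concentration, stage_cfg("location"))
    loc_tab <- summarize_posterior(loc$samples, "mu_log", transform = exp,
                                   label = "mu")
    warn_rhat(loc_tab, "location")
    write_summary_table(loc_tab, file.path(outdir, "location_summary.csv"))
    bundle$location <- list(fit = loc, summary = loc_tab)
    log_stage("location", sprintf("n = %d, geometric mean %.2f ng/g",
                                  nrow(test_rec), loc_tab$`50.0%`[1]))
  }
  if (nrow(test_rec) >= 5L) {
    aug <- augment_winter_replication(test_rec, winter_window)
    sfit <- fit_seasonal(aug, stage_cfg("seasonal"))
    stab <- summarize_seasonal(sfit)
    warn_rhat(stab, "seasonal")
    br2 <- bayesian_r2(sfit)
    band <- predict_band(sfit)
    write_summary_table(stab, file.path(outdir, "seasonal_summary.csv"))
    utils::write.csv(as.data.frame(band),
                     file.path(outdir, "seasonal_band.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(p_positive_amplitude = sfit$p_positive_amplitude,
                 peak_day_median = sfit$peak_day_median,
                 br2 = br2$mean, br2_lo95 = br2$ci95[1],
                 br2_hi95 = br2$ci95[2]),
      file.path(outdir, "seasonal_stats.csv"), row.names = FALSE)
    bundle$seasonal <- list(fit = sfit, summary = stab, br2 = br2,
                            band = band)
    log_stage("seasonal",
              sprintf("n = %d (+%d winter replicates), peak day %.0f, P(A>0) = %.2f",
                      nrow(test_rec), nrow(aug) - nrow(test_rec),
                      sfit$peak_day_median, sfit$p_positive_amplitude))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("blubberBayes")),
    seed = seed,
    stage_seeds = list(mixture = split_seed(seed, "mixture"),
                       location = split_seed(seed, "location"),
                       seasonal = split_seed(seed, "seasonal"),
                       accuracy = split_seed(seed, "accuracy")),
    chain_config = unclass(config)[c("n_chains", "n_iterations",
                                     "burn_in_fraction", "thin")],
    retained_samples = retained_sample_count(config),
    winter_window = winter_window,
    inputs = list(hormone_csv = input, plate_csv = plate_csv,
                  accuracy_csv = accuracy_csv),
    n_records = nrow(data))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Materialize canonical synthetic fixture datasets
#'
#' Writes seeded CSV fixtures (and a manifest of the generating
#' parameters) for the mixture, seasonal and assay generators.
#'
#' @param preset one of `"mixture"`, `"seasonal"`, `"assay"`, `"all"`.
#' @param seed integer seed.
#' @param outdir output directory (created if missing).
#' @param n optional override of the number of records for the mixture and
#'   seasonal presets.
#' @return Invisibly, the character vector of files written.
#' @export
simulate_fixtures <- function(preset = c("all", "mixture", "seasonal",
                                         "assay"),
                              seed = 1L, outdir = ".", n = NULL) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e)
                       stop("unknown preset; choose one of: all, mixture, ",
                            "seasonal, assay", call. = FALSE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  params <- list()
  if (preset %in% c("all", "mixture")) {
    p <- mixture_sim_params(n = n %||% 34L, seed = split_seed(seed, "mixture"))
    g <- gen_mixture_concentrations(p)
    g$dataset$true_cluster <- g$true_labels
    f <- file.path(outdir, "synthetic_progesterone.csv")
    write_hormone_csv(g$dataset, f)
    files <- c(files, f)
    params$mixture <- unclass(p)
  }
  if (preset %in% c("all", "seasonal")) {
    p <- seasonal_sim_params(n = n %||% 44L,
                             seed = split_seed(seed, "seasonal"))
    f <- file.path(outdir, "synthetic_testosterone.csv")
    write_hormone_csv(gen_seasonal_concentrations(p), f)
    files <- c(files, f)
    params$seasonal <- unclass(p)
  }
  if (preset %in% c("all", "assay")) {
    p <- assay_sim_params(seed = split_seed(seed, "assay"))
    g <- gen_assay_series(p)
    f <- file.path(outdir, c("synthetic_accuracy.csv",
                             "synthetic_standard_curve.csv",
                             "synthetic_dilution_series.csv"))
    utils::write.csv(g$accuracy, f[1], row.names = FALSE)
    utils::write.csv(g$standard_curve, f[2], row.names = FALSE)
    utils::write.csv(g$dilution_series, f[3], row.names = FALSE)
    files <- c(files, f)
    params$assay <- unclass(p)
  }
  mf <- file.path(outdir, "fixture_manifest.json")
  jsonlite::write_json(list(preset = preset, seed = seed, params = params),
                       mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, mf))
}
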