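# Sinusoidal day-of-year model: winter replication, peak recovery,
# positive-amplitude probability, Bayesian R2, and prediction bands.

test_that("winter replication duplicates only the window, flagged and shifted", {
  d <- hormone_dataset(
    whale_id = sprintf("M%02d", 1:10), sex = "male", hormone = "testosterone",
    concentration = seq(0.5, 5, length.out = 10),
    date = as.Date("2016-01-01") + c(39, 199, 10, 80, 120, 160, 220, 260,
                                     300, 340))
  aug <- augment_winter_replication(d, c(1, 90))
  expect_equal(nrow(aug), 13L)               # 3 winter records duplicated
  expect_equal(sum(aug$replicated), 3L)
  reps <- aug[aug$replicated, ]
  expect_setequal(reps$day_of_year, c(40, 11, 81) + 365)
  # originals untouched
  expect_identical(as.data.frame(aug[1:10, ]), as.data.frame(d))
  # records outside the window are never duplicated
  aug2 <- augment_winter_replication(d[d$day_of_year > 180, ], c(1, 90))
  expect_equal(nrow(aug2), sum(d$day_of_year > 180))
  expect_error(augment_winter_replication(d, c(100, 50)), "interval")
})

test_that("strong seasonal signal: peak day recovered, amplitude certain", {
  p <- seasonal_sim_params(n = 84, alpha = 0, amplitude = 1.0,
                           peak_day = 227, sigma = 0.7,
                           day_range = c(30, 300), seed = 11)
  d <- gen_seasonal_concentrations(p)
  fit <- fit_seasonal(augment_winter_replication(d), cfg_test(42))
  expect_lt(abs(fit$peak_day_median - 227), 15)
  expect_equal(fit$p_positive_amplitude, 1)
  expect_gt(fit$trend_coherence, 0.99)
  tab <- summarize_seasonal(fit)
  expect_true(all(tab$Rhat < 1.05, na.rm = TRUE))
  # amplitude CI covers the generating value
  amp <- tab[tab$parameter == "amplitude", ]
  expect_true(amp$`2.5%` <= 1 && 1 <= amp$`97.5%`)
  expect_error(fit_seasonal(d[rep(1, 6), ]), "unidentifiable")
})

test_that("noiseless four-point cosine is interpolated to the truth", {
  days <- c(46, 137, 228, 319)
  mu <- 0.3 + 0.8 * cos(2 * pi * (days - 227) / 365)
  d <- data.frame(day_of_year = rep(days, 3),
                  concentration = exp(rep(mu, 3) +
                                        rnorm(12, 0, 1e-6)))
  fit <- fit_seasonal(d, cfg_light(4))
  dr <- do.call(rbind, fit$samples$draws)
  expect_lt(abs(stats::median(dr[, "alpha"]) - 0.3), 0.01)
  expect_lt(abs(stats::median(dr[, "amplitude_canonical"]) - 0.8), 0.01)
  expect_lt(abs(fit$peak_day_median - 227), 2)
})

test_that("amplitude-0 null: positive-amplitude probability is centred on 1/2
          over replicate datasets", {
  ps <- vapply(1:20, function(s) {
    p <- seasonal_sim_params(n = 200, alpha = 0, amplitude = 0,
                             peak_day = 180, sigma = 0.7,
                             day_range = c(1, 365), seed = s)
    fit <- fit_seasonal(augment_winter_replication(
      gen_seasonal_concentrations(p)), cfg_light(s))
    fit$p_positive_amplitude
  }, 0)
  expect_true(all(ps >= 0 & ps <= 1))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("Bayesian R2 has the right limits and tracks the variance ratio", {
  # noiseless limit -> 1
  days <- seq(20, 340, by = 20)
  d0 <- data.frame(day_of_year = days,
                   concentration = exp(cos(2 * pi * (days - 200) / 365) +
                                         rnorm(length(days), 0, 1e-6)))
  f0 <- fit_seasonal(d0, cfg_light(1))
  expect_gt(bayesian_r2(f0)$mean, 0.999)
  # flat draw -> 0 by construction of the formula
  fit_null <- f0
  d <- fit_null$samples$draws[[1]][1, , drop = FALSE]
  mu_flat <- blubberBayes:::seasonal_mean(days, d[, "alpha"], 0, d[, "phi"])
  expect_equal(stats::var(mu_flat), 0)
  # signal:total variance 1:4 -> BR2 ~ 0.25; Var(A cos) = A^2/2 over uniform
  # days, so A = sqrt(2)/2 and sigma^2 = 3 * A^2/2
  A <- sqrt(0.5); sigma <- sqrt(3 * A^2 / 2)
  p <- seasonal_sim_params(n = 500, alpha = 0, amplitude = A,
                           peak_day = 227, sigma = sigma,
                           day_range = c(1, 365), seed = 6)
  fit <- fit_seasonal(gen_seasonal_concentrations(p),
                      chain_config(2, 6000, 0.1, 3, seed = 6))
  expect_lt(abs(bayesian_r2(fit)$mean - 0.25), 0.05)
})

test_that("prediction bands are periodic, nested, and peak in the right month", {
  p <- seasonal_sim_params(n = 84, alpha = 0, amplitude = 1.0,
                           peak_day = 227, sigma = 0.7,
                           day_range = c(30, 300), seed = 11)
  fit <- fit_seasonal(augment_winter_replication(
    gen_seasonal_concentrations(p)), cfg_light(7))
  band <- predict_band(fit, grid = 1:365)
  expect_true(all(band$lo95 <= band$lo75 & band$lo75 <= band$hi75 &
                    band$hi75 <= band$hi95))
  expect_true(all(band$lo75 <= band$median & band$median <= band$hi75))
  # periodicity: day d and d + 365 give identical bands
  b2 <- predict_band(fit, grid = c(10, 375))
  expect_equal(unlist(b2[1, -1]), unlist(b2[2, -1]), tolerance = 1e-12)
  # posterior-mean curve peaks in August (days 213-243) for this signal
  expect_true(attr(band, "peak_day") >= 213 && attr(band, "peak_day") <= 243)
  # point-mass posterior: zero-width bands equal to the curve
  pm <- fit
  one <- fit$samples$draws[[1]][1, , drop = FALSE]
  cfg1 <- chain_config(1, 1, 0, 1, seed = 1)
  pm$samples <- blubberBayes:::new_posterior_samples(list(one), cfg1)
  bpm <- predict_band(pm, grid = c(50, 227))
  expect_equal(bpm$lo95, bpm$hi95)
  expect_equal(bpm$median,
               exp(blubberBayes:::seasonal_mean(c(50, 227), one[, "alpha"],
                                                one[, "A"], one[, "phi"])))
  # predictive bands are wider than mean-curve bands
  bp <- predict_band(fit, grid = c(50, 227), type = "predictive")
  bm <- predict_band(fit, grid = c(50, 227))
  expect_true(all(bp$hi95 - bp$lo95 > bm$hi95 - bm$lo95))
})

test_that("replicating winter records equals doubling their likelihood weight", {
  p <- seasonal_sim_params(n = 60, alpha = 0, amplitude = 1.0,
                           peak_day = 227, sigma = 0.7,
                           day_range = c(1, 365), seed = 19)
  d <- gen_seasonal_concentrations(p)
  aug <- augment_winter_replication(d, c(1, 90))
  # same records duplicated at their original day (model is 365-periodic)
  win <- d[d$day_of_year <= 90, ]
  win$replicated <- TRUE
  dbl <- rbind(as.data.frame(d), as.data.frame(win))
  class(dbl) <- c("hormone_dataset", "data.frame")
  f1 <- fit_seasonal(aug, cfg_light(3))
  f2 <- fit_seasonal(dbl, cfg_light(3))
  expect_lt(abs(f1$peak_day_median - f2$peak_day_median), 3)
  t1 <- summarize_seasonal(f1); t2 <- summarize_seasonal(f2)
  expect_equal(t1$Mean, t2$Mean, tolerance = 0.05)
})
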