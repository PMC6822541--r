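# Sampler correctness against closed-form targets, chain bookkeeping,
# and the convergence diagnostics.

test_that("retained draw counts follow chains * floor(iters*(1-burn)/thin)", {
  expect_identical(retained_sample_count(publication_chain_config()), 135000L)
  expect_identical(retained_sample_count(chain_config(1, 1000, 0.1, 1)),
                   900L)
  expect_identical(retained_sample_count(chain_config(2, 10000, 0.1, 20)),
                   900L)
  s <- sample_posterior(function(th) -th^2 / 2, 0,
                        chain_config(2, 500, 0.1, 3, seed = 1))
  expect_identical(s$n_retained, retained_sample_count(s$config))
})

test_that("sampler reproduces a standard normal target", {
  s <- sample_posterior(function(th) stats::dnorm(th, log = TRUE), 0.5,
                        chain_config(3, 20000, 0.1, 2, seed = 4),
                        param_names = "x")
  x <- posterior_draws(s, "x")
  mcse <- stats::sd(x) / sqrt(effective_sample_size(s, "x")$neff)
  expect_lt(abs(mean(x)), 3 * mcse)
  expect_lt(abs(stats::sd(x) - 1), 0.05)
})

test_that("sampler matches the conjugate normal-mean posterior", {
  # y ~ N(mu, 1), mu ~ N(0, 10^2): posterior N(sum(y)/(n + 1/100), 1/(n + 1/100))
  y <- c(1.2, 0.4, 2.1, 1.7, 0.9)
  tau2 <- 100
  post_var <- 1 / (length(y) + 1 / tau2)
  post_mean <- sum(y) * post_var
  lp <- function(mu) sum(stats::dnorm(y, mu, 1, log = TRUE)) +
    stats::dnorm(mu, 0, sqrt(tau2), log = TRUE)
  s <- sample_posterior(lp, mean(y), chain_config(3, 10000, 0.1, 2, seed = 8),
                        param_names = "mu")
  mu <- posterior_draws(s, "mu")
  mcse <- stats::sd(mu) / sqrt(effective_sample_size(s, "mu")$neff)
  expect_lt(abs(mean(mu) - post_mean), 3 * mcse)
  expect_lt(abs(stats::sd(mu) - sqrt(post_var)), 0.05 * sqrt(post_var))
})

test_that("sampler matches the Beta-Bernoulli posterior", {
  # 7 successes in 10 trials, Beta(2,2) prior -> Beta(9,5); sample logit(p)
  lp <- function(v) {
    p <- stats::plogis(v)
    7 * log(p) + 3 * log1p(-p) + stats::dbeta(p, 2, 2, log = TRUE) +
      log(p) + log1p(-p)
  }
  s <- sample_posterior(lp, 0, chain_config(3, 10000, 0.1, 2, seed = 3),
                        param_names = "v")
  p <- stats::plogis(posterior_draws(s, "v"))
  expect_lt(abs(mean(p) - 9 / 14), 0.01)
  for (q in c(0.1, 0.5, 0.9))
    expect_lt(abs(stats::quantile(p, q, type = 1, names = FALSE) -
                    stats::qbeta(q, 9, 5)), 0.02)
  expect_error(sample_posterior(function(th) -Inf, 0, cfg_mini(1)),
               "not finite")
})

test_that("Gelman-Rubin flags offset chains and passes converged ones", {
  cfg <- chain_config(3, 2000, 0, 1, seed = 1)
  draws <- lapply(1:3, function(i) {
    set.seed(i)
    matrix(rnorm(2000), ncol = 1, dimnames = list(NULL, "x"))
  })
  s <- blubberBayes:::new_posterior_samples(draws, cfg)
  r <- gelman_rubin(s, "x")
  expect_gte(r, 0.999)   # can sit a hair under 1 by finite-sample noise
  expect_lt(r, 1.01)

  draws_off <- draws
  draws_off[[2]][, 1] <- draws_off[[2]][, 1] + 10
  s_off <- blubberBayes:::new_posterior_samples(draws_off, cfg)
  expect_gt(gelman_rubin(s_off, "x"), 1.5)

  const <- lapply(1:3, function(i)
    matrix(1.5, 2000, 1, dimnames = list(NULL, "x")))
  s_const <- blubberBayes:::new_posterior_samples(const, cfg)
  expect_equal(gelman_rubin(s_const, "x"), 1)

  cfg1 <- chain_config(1, 2000, 0, 1, seed = 1)
  s1 <- blubberBayes:::new_posterior_samples(draws[1], cfg1)
  expect_error(gelman_rubin(s1, "x"), "2 chains")
})

test_that("effective sample size matches iid and AR(1) closed forms", {
  cfg <- chain_config(2, 5000, 0, 1, seed = 1)
  iid <- lapply(1:2, function(i) {
    set.seed(10 + i)
    matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "x"))
  })
  s <- blubberBayes:::new_posterior_samples(iid, cfg)
  expect_gt(effective_sample_size(s, "x")$neff_percent, 85)
  expect_lte(effective_sample_size(s, "x")$neff_percent, 100)

  # AR(1) with rho = 0.5: ESS = n (1-rho)/(1+rho) = n/3
  ar <- lapply(1:2, function(i) {
    set.seed(20 + i)
    matrix(as.numeric(stats::arima.sim(list(ar = 0.5), 5000)), ncol = 1,
           dimnames = list(NULL, "x"))
  })
  s_ar <- blubberBayes:::new_posterior_samples(ar, cfg)
  neff <- effective_sample_size(s_ar, "x")$neff
  expect_lt(abs(neff - 10000 / 3) / (10000 / 3), 0.15)

  # antithetic alternating sequence: finite, positive, capped
  alt <- lapply(1:2, function(i)
    matrix(rep(c(1, -1), 2500), ncol = 1, dimnames = list(NULL, "x")))
  s_alt <- blubberBayes:::new_posterior_samples(alt, cfg)
  e <- effective_sample_size(s_alt, "x")
  expect_true(is.finite(e$neff) && e$neff > 0)
  expect_lte(e$neff_percent, 100)
})

test_that("summaries commute with monotone transforms (inverse-ECDF quantiles)", {
  cfg <- chain_config(2, 3000, 0, 1, seed = 1)
  draws <- lapply(1:2, function(i) {
    set.seed(30 + i)
    matrix(rnorm(3000), ncol = 1, dimnames = list(NULL, "x"))
  })
  s <- blubberBayes:::new_posterior_samples(draws, cfg)
  raw <- summarize_posterior(s, "x")
  ex <- summarize_posterior(s, "x", transform = exp)
  qcols <- c("2.5%", "25.0%", "50.0%", "75.0%", "97.5%")
  expect_identical(unname(unlist(ex[qcols])), exp(unname(unlist(raw[qcols]))))
  expect_true(!is.unsorted(unlist(ex[qcols])))
  # standard normal draws under exp: log-normal quantile closed form
  expect_equal(ex$`50.0%`, 1, tolerance = 0.05)
  expect_equal(ex$`97.5%`, exp(1.96), tolerance = 0.1)
  expect_equal(ex$`2.5%`, exp(-1.96), tolerance = 0.1)
})
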