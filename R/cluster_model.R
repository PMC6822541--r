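# Stage 1 of the analysis: a two-component Bayesian normal mixture on
# log-progesterone (cluster A = low concentrations, cluster B = high), and
# a simple Bayesian log-normal location model for testosterone.
#
# The mixture likelihood is marginalized over the latent cluster
# indicators; per-animal indicator draws are recovered afterwards from
# their exact conditional Bernoulli distribution given each retained draw.

mixture_loglik <- function(ly) {
  force(ly)
  function(th) {
    s1 <- exp(th[3]); s2 <- exp(th[4]); w <- stats::plogis(th[5])
    l1 <- stats::dnorm(ly, th[1], s1, log = TRUE) + log1p(-w)
    l2 <- stats::dnorm(ly, th[2], s2, log = TRUE) + log(w)
    m <- pmax.int(l1, l2)
    sum(m + log1p(exp(pmin.int(l1, l2) - m)))
  }
}

#' Fit a two-component Bayesian normal mixture to log-concentrations
#'
#' Models `log(y_i)` as a mixture
#' `(1 - w_B) N(m_A, s_A^2) + w_B N(m_B, s_B^2)`. Default priors:
#' `m_A, m_B ~ N(0, 10^2)`, `s_A, s_B ~ Half-Normal(0, 5)`,
#' `w_B ~ Uniform(0, 1)`. The label symmetry is resolved per retained draw
#' by relabelling so that `m_A < m_B` (ordered-means constraint), which
#' leaves all label-invariant quantities untouched. Per-animal cluster
#' indicator draws `z_i` are sampled from their exact conditional given
#' each retained draw.
#'
#' @param concentrations positive numeric, ng per g blubber (>= 4 values,
#'   not all identical).
#' @param config a [chain_config()].
#' @param priors optional list overriding `mean_sd` (default 10),
#'   `sd_scale` (default 5) of the half-normal on the cluster SDs.
#' @param fixed_sd optional: fix both cluster SDs at this value and sample
#'   only the means and weight (used for oracle comparisons on tiny data).
#' @return A `mixture_fit`: `samples` over
#'   `m_A, m_B, s_A, s_B, w_B`, indicator draws `z` (draws x n matrix,
#'   TRUE = cluster B), the data, and the configuration.
#' @export
fit_mixture <- function(concentrations, config = chain_config(),
                        priors = NULL, fixed_sd = NULL) {
  if (length(concentrations) < 4L)
    stop("need at least 4 observations", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  if (stats::sd(concentrations) == 0)
    stop("all observations identical: mixture likelihood is degenerate",
         call. = FALSE)
  mean_sd <- priors$mean_sd %||% 10
  sd_scale <- priors$sd_scale %||% 5
  ly <- log(concentrations)
  ll <- mixture_loglik(ly)

  if (is.null(fixed_sd)) {
    lp <- function(th) {
      s1 <- exp(th[3]); s2 <- exp(th[4]); w <- stats::plogis(th[5])
      ll(th) +
        stats::dnorm(th[1], 0, mean_sd, log = TRUE) +
        stats::dnorm(th[2], 0, mean_sd, log = TRUE) +
        stats::dnorm(s1, 0, sd_scale, log = TRUE) + th[3] +
        stats::dnorm(s2, 0, sd_scale, log = TRUE) + th[4] +
        log(w) + log1p(-w)                      # uniform weight, logit Jacobian
    }
    qs <- stats::quantile(ly, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
    s0 <- log(max(stats::sd(ly) / 2, 0.1))
    base_inits <- list(c(qs[2], qs[4], s0, s0, 0),
                       c(qs[1], qs[5], s0, s0, 0),
                       c(qs[3] - 0.5, qs[3] + 0.5, s0, s0, 0))
    inits <- lapply(seq_len(config$n_chains), function(c)
      base_inits[[(c - 1L) %% 3L + 1L]])
    raw <- sample_posterior(lp, inits, config,
                            param_names = c("m_A", "m_B", "u_A", "u_B", "v"),
                            scale0 = c(0.3, 0.3, 0.3, 0.3, 0.5))
    draws <- lapply(raw$draws, function(m) {
      out <- cbind(m_A = m[, "m_A"], m_B = m[, "m_B"],
                   s_A = exp(m[, "u_A"]), s_B = exp(m[, "u_B"]),
                   w_B = stats::plogis(m[, "v"]))
      relabel_ordered(out)
    })
  } else {
    stopifnot(fixed_sd > 0)
    lp <- function(th) {
      w <- stats::plogis(th[3])
      th5 <- c(th[1], th[2], log(fixed_sd), log(fixed_sd), th[3])
      ll(th5) +
        stats::dnorm(th[1], 0, mean_sd, log = TRUE) +
        stats::dnorm(th[2], 0, mean_sd, log = TRUE) +
        log(w) + log1p(-w)
    }
    qs <- stats::quantile(ly, c(0.25, 0.75), names = FALSE)
    inits <- lapply(seq_len(config$n_chains), function(c)
      c(qs[1] - 0.2 * (c - 1), qs[2] + 0.2 * (c - 1), 0))
    raw <- sample_posterior(lp, inits, config,
                            param_names = c("m_A", "m_B", "v"),
                            scale0 = c(0.3, 0.3, 0.5))
    draws <- lapply(raw$draws, function(m) {
      out <- cbind(m_A = m[, "m_A"], m_B = m[, "m_B"],
                   s_A = rep(fixed_sd, nrow(m)), s_B = rep(fixed_sd, nrow(m)),
                   w_B = stats::plogis(m[, "v"]))
      relabel_ordered(out)
    })
  }
  samples <- new_posterior_samples(draws, config)
  z <- draw_indicators(samples, ly)
  structure(list(samples = samples, z = z, log_concentrations = ly,
                 n = length(ly), config = config),
            class = "mixture_fit")
}

# enforce m_A < m_B per draw by swapping labels
relabel_ordered <- function(m) {
  swap <- m[, "m_A"] > m[, "m_B"]
  if (any(swap)) {
    tmp <- m[swap, c("m_B", "m_A", "s_B", "s_A"), drop = FALSE]
    m[swap, c("m_A", "m_B", "s_A", "s_B")] <- tmp
    m[swap, "w_B"] <- 1 - m[swap, "w_B"]
  }
  m
}

# conditional probability that each observation belongs to cluster B,
# given one parameter draw (row of the draws matrix)
cond_prob_B <- function(ly, m_A, m_B, s_A, s_B, w_B) {
  l1 <- stats::dnorm(ly, m_A, s_A, log = TRUE) + log1p(-w_B)
  l2 <- stats::dnorm(ly, m_B, s_B, log = TRUE) + log(w_B)
  1 / (1 + exp(l1 - l2))
}

draw_indicators <- function(samples, ly) {
  all_draws <- do.call(rbind, samples$draws)
  with_seed(split_seed(samples$config$seed, "indicator-draws"), {
    z <- matrix(FALSE, nrow(all_draws), length(ly))
    for (i in seq_len(nrow(all_draws))) {
      p <- cond_prob_B(ly, all_draws[i, "m_A"], all_draws[i, "m_B"],
                       all_draws[i, "s_A"], all_draws[i, "s_B"],
                       all_draws[i, "w_B"])
      z[i, ] <- stats::runif(length(ly)) < p
    }
    z
  })
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture_fit: n = %d, %d retained draws\n",
              x$n, x$samples$n_retained))
  print(summarize_mixture(x))
  invisible(x)
}

#' Posterior summary of the mixture cluster means on the concentration scale
#'
#' Table rows for the exponentiated cluster means (geometric means, ng/g),
#' in the standard posterior-summary layout.
#'
#' @param fit a `mixture_fit`.
#' @return A `posterior_summary` with rows `mu_ClusterA`, `mu_ClusterB`.
#' @export
summarize_mixture <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  bind_summaries(
    summarize_posterior(fit$samples, "m_A", transform = exp,
                        label = "mu_ClusterA"),
    summarize_posterior(fit$samples, "m_B", transform = exp,
                        label = "mu_ClusterB"))
}

#' Posterior probability that a concentration arose from cluster B
#'
#' For each value `v`, averages over retained draws the conditional
#' probability `w_B N(log v | m_B, s_B) / [(1-w_B) N(log v | m_A, s_A) +
#' w_B N(log v | m_B, s_B)]`. `P(A|v) = 1 - P(B|v)` exactly.
#'
#' @param fit a `mixture_fit`.
#' @param value positive concentration(s), ng per g.
#' @return Numeric vector of posterior mean probabilities of cluster B.
#' @export
cluster_source_probability <- function(fit, value) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (any(value <= 0)) stop("value must be > 0", call. = FALSE)
  d <- do.call(rbind, fit$samples$draws)
  vapply(log(value), function(lv) {
    mean(cond_prob_B(lv, d[, "m_A"], d[, "m_B"], d[, "s_A"], d[, "s_B"],
                     d[, "w_B"]))
  }, 0)
}

#' Posterior distribution of cluster occurrence among sampled animals
#'
#' Per retained draw, the realized fraction of sampled animals whose
#' indicator lies in each cluster; summarized with posterior mean and 95%
#' credible interval.
#'
#' @param fit a `mixture_fit`.
#' @return List with `fraction_A_draws`, `fraction_A` (mean),
#'   `fraction_A_ci95`, and the complementary `fraction_B` quantities.
#' @export
cluster_occurrence <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  fB <- rowMeans(fit$z)
  fA <- 1 - fB
  list(fraction_A_draws = fA,
       fraction_A = mean(fA),
       fraction_A_ci95 = stats::quantile(fA, c(0.025, 0.975), type = 1,
                                         names = FALSE),
       fraction_B = mean(fB),
       fraction_B_ci95 = stats::quantile(fB, c(0.025, 0.975), type = 1,
                                         names = FALSE))
}

#' Simple Bayesian estimation of a log-normal mean
#'
#' Models `log(y_i) ~ N(mu_log, sigma_log^2)` with defaults
#' `mu_log ~ N(0, 10^2)` and `sigma_log ~ Half-Normal(0, 5)`; summaries are
#' reported as `exp(mu_log)` (the geometric mean, ng per g).
#'
#' @param concentrations positive numeric (>= 2 values).
#' @param config a [chain_config()].
#' @param priors optional list overriding `mean_sd`, `sd_scale`.
#' @return A `location_fit` with `samples` over `mu_log`, `sigma_log`.
#' @export
fit_lognormal_mean <- function(concentrations, config = chain_config(),
                               priors = NULL) {
  if (length(concentrations) < 2L)
    stop("need at least 2 observations", call. = FALSE)
  if (any(concentrations <= 0))
    stop("concentrations must be strictly positive", call. = FALSE)
  mean_sd <- priors$mean_sd %||% 10
  sd_scale <- priors$sd_scale %||% 5
  ly <- log(concentrations)
  lp <- function(th) {
    sigma <- exp(th[2])
    sum(stats::dnorm(ly, th[1], sigma, log = TRUE)) +
      stats::dnorm(th[1], 0, mean_sd, log = TRUE) +
      stats::dnorm(sigma, 0, sd_scale, log = TRUE) + th[2]
  }
  s_obs <- max(stats::sd(ly), 1e-3)
  inits <- lapply(seq_len(config$n_chains), function(c)
    c(mean(ly) + 0.25 * (c - 1) * s_obs, log(s_obs) + 0.2 * (c - 1)))
  samples <- sample_posterior(lp, inits, config,
                              param_names = c("mu_log", "u"),
                              scale0 = c(s_obs / sqrt(length(ly)) * 3, 0.3))
  draws <- lapply(samples$draws, function(m) {
    out <- cbind(mu_log = m[, "mu_log"], sigma_log = exp(m[, "u"]))
    out
  })
  structure(list(samples = new_posterior_samples(draws, config),
                 log_concentrations = ly, config = config),
            class = "location_fit")
}

#' @export
print.location_fit <- function(x, ...) {
  cat(sprintf("location_fit: n = %d, %d retained draws\n",
              length(x$log_concentrations), x$samples$n_retained))
  print(summarize_posterior(x$samples, "mu_log", transform = exp,
                            label = "mu"))
  invisible(x)
}
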