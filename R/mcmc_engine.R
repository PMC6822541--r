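# Posterior sampling machinery shared by all models: chain management,
# burn-in/thinning bookkeeping, convergence diagnostics and posterior
# summaries in the layout used for hormone-mean tables
# (Mean, SD, 2.5%, 25%, 50%, 75%, 97.5%, Rhat, Neff %).

#' MCMC chain configuration
#'
#' Bundles the chain settings shared by every model fit: number of
#' independent chains, iterations per chain, the burn-in fraction discarded
#' from the start of each chain, the thinning interval and the RNG seed.
#'
#' The publication-scale configuration used for the whale hormone analyses
#' (3 chains of 1,000,000 iterations, 10% burn-in, thin 20, hence 135,000
#' retained draws) is available via `publication_chain_config()`; the default here
#' is a lighter configuration suitable for tests and interactive work.
#'
#' @param n_chains number of independent chains (>= 1).
#' @param n_iterations iterations per chain.
#' @param burn_in_fraction fraction of each chain discarded as burn-in
#'   (in `[0, 1)`). Proposal-scale adaptation happens only during burn-in.
#' @param thin keep one draw of every `thin` post-burn-in iterations.
#' @param seed integer RNG seed; chain `c` uses a seed derived from
#'   `seed` and `c`, so runs are reproducible and chains independent.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(n_chains = 3L, n_iterations = 20000L,
                         burn_in_fraction = 0.1, thin = 5L, seed = 1L) {
  n_chains <- as.integer(n_chains)
  n_iterations <- as.integer(n_iterations)
  thin <- as.integer(thin)
  stopifnot(n_chains >= 1L, n_iterations >= 1L, thin >= 1L,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  structure(list(n_chains = n_chains, n_iterations = n_iterations,
                 burn_in_fraction = burn_in_fraction, thin = thin,
                 seed = as.integer(seed)),
            class = "chain_config")
}

#' @rdname chain_config
#' @export
publication_chain_config <- function(seed = 1L) {
  chain_config(n_chains = 3L, n_iterations = 1000000L,
               burn_in_fraction = 0.1, thin = 20L, seed = seed)
}

#' @export
print.chain_config <- function(x, ...) {
  cat(sprintf(
    "chain_config: %d chains x %d iterations, %.0f%% burn-in, thin %d, seed %d\n",
    x$n_chains, x$n_iterations, 100 * x$burn_in_fraction, x$thin, x$seed))
  cat(sprintf("  retained draws: %d\n", retained_sample_count(x)))
  invisible(x)
}

#' Total retained posterior draws implied by a chain configuration
#'
#' `n_chains * floor(n_iterations * (1 - burn_in_fraction) / thin)`.
#' With 3 chains of 1,000,000 iterations, 10% burn-in and thinning of 20
#' this is 135,000.
#'
#' @param config a [chain_config()].
#' @return Integer count of retained draws across all chains.
#' @export
retained_sample_count <- function(config) {
  stopifnot(inherits(config, "chain_config"))
  per_chain <- floor(config$n_iterations * (1 - config$burn_in_fraction) /
                       config$thin)
  as.integer(config$n_chains * per_chain)
}

# ---- posterior_samples container ----------------------------------------

# draws: list (one per chain) of [retained x n_param] matrices with
# identical column names. Invariant: total rows == retained_sample_count.
new_posterior_samples <- function(draws, config, accept_rate = NULL) {
  stopifnot(is.list(draws), length(draws) == config$n_chains)
  pn <- colnames(draws[[1L]])
  total <- sum(vapply(draws, nrow, 0L))
  if (total != retained_sample_count(config))
    stop("internal error: retained draw count does not match configuration")
  structure(list(draws = draws, param_names = pn, config = config,
                 n_retained = total, accept_rate = accept_rate),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d parameters (%s), %d chains, %d retained draws\n",
              length(x$param_names), paste(x$param_names, collapse = ", "),
              x$config$n_chains, x$n_retained))
  invisible(x)
}

#' Extract retained draws
#'
#' @param samples a `posterior_samples` object.
#' @param parameter parameter name.
#' @param by_chain if `TRUE`, return a list of per-chain vectors; otherwise
#'   one concatenated vector.
#' @return Numeric vector (or list of vectors) of retained draws.
#' @export
posterior_draws <- function(samples, parameter, by_chain = FALSE) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!parameter %in% samples$param_names)
    stop(sprintf("unknown parameter '%s' (available: %s)", parameter,
                 paste(samples$param_names, collapse = ", ")), call. = FALSE)
  per <- lapply(samples$draws, function(m) m[, parameter])
  if (by_chain) per else unlist(per, use.names = FALSE)
}

# Build a posterior_samples-like object for a quantity derived draw-by-draw
# from an existing one (keeps the chain structure so Rhat/ESS still apply).
# fun maps a per-chain draw matrix to a numeric vector of the same length.
derive_parameter <- function(samples, name, fun) {
  draws <- lapply(samples$draws, function(m) {
    v <- fun(m)
    mat <- matrix(v, ncol = 1L)
    colnames(mat) <- name
    mat
  })
  new_posterior_samples(draws, samples$config)
}

# ---- sampler -------------------------------------------------------------

#' Sample from a log-posterior with adaptive random-walk Metropolis
#'
#' Generic MCMC used by every model in the package. Each chain performs
#' component-wise Gaussian random-walk Metropolis updates; per-component
#' proposal scales are adapted toward an acceptance rate of 0.44 during the
#' burn-in phase only (Robbins-Monro on the log scale), so the retained
#' chain is a draw from a fixed, valid kernel. The contract is correctness
#' of the stationary distribution, not any particular transition kernel.
#'
#' @param log_posterior function taking a parameter vector and returning the
#'   unnormalized log posterior density (may return `-Inf` outside the
#'   support).
#' @param init numeric vector, or list of per-chain numeric vectors, of
#'   initial values; `log_posterior` must be finite at every init.
#' @param config a [chain_config()].
#' @param param_names optional character vector of parameter names.
#' @param wrap optional function applied to each proposal before evaluation,
#'   used to fold circular parameters back into their fundamental domain
#'   (e.g. a phase into `[0, 365)`); it must be a symmetry of the target.
#' @param scale0 optional initial proposal scales (recycled over parameters).
#' @return A `posterior_samples` object.
#' @export
sample_posterior <- function(log_posterior, init, config,
                             param_names = NULL, wrap = NULL, scale0 = NULL) {
  stopifnot(inherits(config, "chain_config"))
  if (!is.list(init)) init <- rep(list(as.numeric(init)), config$n_chains)
  if (length(init) != config$n_chains)
    stop("need one init vector per chain", call. = FALSE)
  d <- length(init[[1L]])
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(d))
  stopifnot(length(param_names) == d)

  n_iter <- config$n_iterations
  n_keep <- floor(n_iter * (1 - config$burn_in_fraction) / config$thin)
  # burn-in chosen so retained count hits the invariant exactly
  n_burn <- n_iter - n_keep * config$thin

  scale0 <- if (is.null(scale0)) rep(1, d) else rep_len(as.numeric(scale0), d)

  run_chain <- function(chain) {
    theta <- as.numeric(init[[chain]])
    if (length(theta) != d) stop("init vectors differ in length", call. = FALSE)
    if (!is.null(wrap)) theta <- wrap(theta)
    lp <- log_posterior(theta)
    if (!is.finite(lp))
      stop("log_posterior is not finite at the initial values of chain ",
           chain, call. = FALSE)
    set.seed(as.integer((as.numeric(config$seed) %% 2147483647 +
                           chain * 1000003) %% 2147483647))
    ls <- log(scale0)
    out <- matrix(NA_real_, n_keep, d, dimnames = list(NULL, param_names))
    acc <- numeric(d)
    acc_total <- 0
    batch <- 50L
    batch_acc <- numeric(d)
    n_batches <- 0L
    kept <- 0L
    for (it in seq_len(n_iter)) {
      for (j in seq_len(d)) {
        prop <- theta
        prop[j] <- prop[j] + exp(ls[j]) * rnorm(1L)
        if (!is.null(wrap)) prop <- wrap(prop)
        lp_prop <- log_posterior(prop)
        if (is.finite(lp_prop) && log(runif(1L)) < lp_prop - lp) {
          theta <- prop
          lp <- lp_prop
          acc[j] <- acc[j] + 1
          batch_acc[j] <- batch_acc[j] + 1
          acc_total <- acc_total + 1
        }
      }
      if (it <= n_burn && it %% batch == 0L) {
        n_batches <- n_batches + 1L
        rate <- batch_acc / batch
        ls <- ls + (rate - 0.44) / sqrt(n_batches)
        batch_acc[] <- 0
      }
      if (it > n_burn && (it - n_burn) %% config$thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- theta
      }
    }
    if (acc_total == 0)
      warning(sprintf("chain %d accepted no proposals; posterior draws are the initial values",
                      chain))
    list(draws = out, accept = acc / (n_iter))
  }

  res <- lapply(seq_len(config$n_chains), run_chain)
  new_posterior_samples(lapply(res, `[[`, "draws"), config,
                        accept_rate = vapply(res, function(r) mean(r$accept), 0))
}

# ---- diagnostics ---------------------------------------------------------

#' Gelman-Rubin potential scale reduction factor (split-chain)
#'
#' Each chain is split in half and the classical between/within-chain
#' variance ratio is computed over the half-chains; values near 1 indicate
#' convergence. Constant chains return exactly 1 by convention.
#'
#' @param samples a `posterior_samples` object with at least 2 chains.
#' @param parameter parameter name.
#' @return The split-chain Rhat (numeric scalar, >= 1 up to rounding).
#' @export
gelman_rubin <- function(samples, parameter) {
  ch <- posterior_draws(samples, parameter, by_chain = TRUE)
  if (length(ch) < 2L)
    stop("Gelman-Rubin diagnostic needs >= 2 chains; run more chains",
         call. = FALSE)
  if (any(vapply(ch, length, 0L) < 10L))
    stop("need >= 10 retained draws per chain", call. = FALSE)
  halves <- unlist(lapply(ch, function(x) {
    n2 <- floor(length(x) / 2)
    list(x[seq_len(n2)], x[n2 + seq_len(n2)])
  }), recursive = FALSE)
  n <- min(vapply(halves, length, 0L))
  halves <- lapply(halves, function(x) x[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps * max(1, abs(mean(means)))^2) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# FFT-based autocovariance (biased, divides by n), lags 0..n-1
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  nf <- 2^ceiling(log2(2 * n))
  f <- stats::fft(c(xc, rep(0, nf - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / nf
  ac[seq_len(n)] / n
}

#' Autocorrelation-based effective sample size
#'
#' Combined-chain effective sample size using per-chain autocovariances and
#' Geyer's initial monotone positive sequence to truncate the
#' autocorrelation sum. `neff` is capped at the retained-draw count, so
#' `neff_percent` lies in `(0, 100]` (the cap also guards antithetic
#' pathologies that would otherwise report more effective than actual
#' draws).
#'
#' @inheritParams gelman_rubin
#' @return List with `neff` and `neff_percent` (100 * neff / retained).
#' @export
effective_sample_size <- function(samples, parameter) {
  ch <- posterior_draws(samples, parameter, by_chain = TRUE)
  if (length(ch) < 2L)
    stop("effective sample size needs >= 2 chains; run more chains",
         call. = FALSE)
  if (any(vapply(ch, length, 0L) < 10L))
    stop("need >= 10 retained draws per chain", call. = FALSE)
  n <- min(vapply(ch, length, 0L))
  ch <- lapply(ch, function(x) x[seq_len(n)])
  m <- length(ch)
  total <- m * n
  means <- vapply(ch, mean, 0)
  vars <- vapply(ch, stats::var, 0)
  W <- mean(vars)
  if (W <= 0) return(list(neff = total, neff_percent = 100))
  B_over_n <- stats::var(means)
  var_plus <- (n - 1) / n * W + B_over_n
  acov <- vapply(ch, autocov_fft, numeric(n))        # n x m
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus              # rho[1] is lag 0
  # Geyer: sum consecutive pairs (lag 2k, 2k+1); stop at first negative pair,
  # enforce nonincreasing pair sums
  max_pairs <- floor((n - 1) / 2)
  tau <- rho[1]                                       # = ~1 at lag 0
  prev_pair <- Inf
  if (max_pairs >= 1) {
    for (k in seq_len(max_pairs)) {
      pair <- rho[2 * k] + rho[2 * k + 1]
      if (!is.finite(pair) || pair < 0) break
      pair <- min(pair, prev_pair)
      prev_pair <- pair
      tau <- tau + 2 * pair
    }
  }
  tau <- max(tau, 1 / total)                         # no negative/zero ESS
  neff <- min(total / tau, total)                    # cap at retained count
  list(neff = neff, neff_percent = 100 * neff / total)
}

# ---- summaries -----------------------------------------------------------

#' Summarize a posterior parameter
#'
#' Mean, SD, the 2.5/25/50/75/97.5% quantiles, split-chain Rhat and
#' effective sample size (as a percentage of retained draws) of
#' `transform(draws)`. Quantiles use the inverse-ECDF rule (`type = 1`), so
#' they commute exactly with monotone transforms:
#' `quantile(exp(x), q) = exp(quantile(x, q))`. For single-chain runs the
#' diagnostic columns are `NA`.
#'
#' @inheritParams gelman_rubin
#' @param transform optional monotone map applied to the draws before
#'   summarizing (default identity; use `exp` to report a log-scale
#'   parameter as a geometric mean in concentration units).
#' @param label row label; defaults to the parameter name.
#' @return A one-row `data.frame` of class `posterior_summary` with columns
#'   `parameter`, `Mean`, `SD`, `2.5%`, `25.0%`, `50.0%`, `75.0%`, `97.5%`,
#'   `Rhat`, `Neff (%)`.
#' @export
summarize_posterior <- function(samples, parameter, transform = identity,
                                label = parameter) {
  x <- transform(posterior_draws(samples, parameter))
  if (length(x) < 10L) stop("need >= 10 draws to summarize", call. = FALSE)
  qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975),
                        type = 1, names = FALSE)
  multi <- samples$config$n_chains >= 2L
  rhat <- if (multi) {
    tr_samples <- derive_parameter(samples, parameter,
                                   function(m) transform(m[, parameter]))
    gelman_rubin(tr_samples, parameter)
  } else NA_real_
  neff_pct <- if (multi) {
    tr_samples <- derive_parameter(samples, parameter,
                                   function(m) transform(m[, parameter]))
    effective_sample_size(tr_samples, parameter)$neff_percent
  } else NA_real_
  out <- data.frame(parameter = label, Mean = mean(x), SD = stats::sd(x),
                    q025 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4],
                    q975 = qs[5], Rhat = rhat, Neff = neff_pct,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("parameter", "Mean", "SD", "2.5%", "25.0%", "50.0%",
                  "75.0%", "97.5%", "Rhat", "Neff (%)")
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Bind posterior summaries into one table
#'
#' @param ... `posterior_summary` rows (or lists of them).
#' @return A multi-row `posterior_summary` data.frame.
#' @export
bind_summaries <- function(...) {
  rows <- list(...)
  rows <- unlist(lapply(rows, function(r) {
    if (inherits(r, "posterior_summary")) list(r) else r
  }), recursive = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("posterior_summary", "data.frame")
  out
}
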