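# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' A single run-level seed fans out to independent per-stage seeds through a
#' fixed multiplicative-congruential rule keyed by a stage label, so each
#' pipeline stage is reproducible both inside [run_full_analysis()] and when
#' run standalone with the seed this function returns.
#'
#' @param seed integer global seed.
#' @param stream character stage label (e.g. `"mixture"`, `"seasonal"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# logsumexp of two vectors, elementwise
lse2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}
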