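# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`, then
#' restores the previous RNG state so library callers never clobber the
#' session stream. All randomized operations in the package route through
#' this helper, which is what makes every result a pure function of
#' `(data, config, seed)`.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 32-bit-safe sub-seed so that independent stages (e.g. one
# hidden layer per sweep point) get decorrelated but reproducible streams.
derive_seed <- function(seed, salt) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(salt) * 16807 + 12345) %%
    2147483647
}

# Numerically stable logistic sigmoid; plogis branches on the sign of the
# argument internally, so large |x| never overflows.
sigmoid <- function(x) stats::plogis(x)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
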