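#' Derive a reproducible sub-seed from a master seed
#'
#' Stages of the pipeline (sampling, degradation, per-patient simulation)
#' draw from independent RNG streams so that, e.g., adding patients to a
#' study does not perturb earlier cases. Each stream's seed is derived from
#' the master seed and a stage label by a small stable string hash
#' (polynomial rolling hash, base 31, modulo 2^31 - 1), so any stage can be
#' re-run in isolation.
#'
#' @param seed integer master seed.
#' @param ... stage labels (coerced to character and concatenated).
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1)),
                 collapse = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1) + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
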