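# Seed plumbing: all randomness in the package flows from one user seed via
# deterministic splitting, so identical seeds reproduce identical output.

#' Derive a child seed from a base seed and a context key
#'
#' Deterministically hashes the base seed together with any number of
#' identifiers (strain names, replicate indices, stage labels) into a new seed
#' in `[1, 2^31 - 2]`.  Used throughout the package so that every stochastic
#' stage has its own reproducible stream.
#'
#' @param seed Base integer seed.
#' @param ... Scalars (coerced to character) identifying the context.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.numeric(seed) %% 2147483647
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h %% 2147483646 + 1)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialise RNG
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
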