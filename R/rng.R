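# Deterministic seed derivation. One master seed fans out into independent
# substreams (population, per-intervention simulation, per-repetition,
# per-trial, PSA) so that components can be re-run in isolation and adding
# interventions or repetitions never perturbs existing draws.

#' Derive a child seed from a master seed
#'
#' Mixes the master seed with a character tag through a small splitmix-style
#' integer hash. Results are stable across platforms and stay below 2^31.
#'
#' @param seed master seed (integer-like scalar).
#' @param ... tags (coerced to character) identifying the substream.
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(tag)) {
    h <- (h * 31 + code) %% 2147483647
  }
  # extra avalanche pass so nearby master seeds decorrelate
  h <- (h * 48271) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  force(seed)  # evaluate caller-supplied draws before snapshotting the RNG
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
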