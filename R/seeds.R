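# Deterministic seed substreams.
#
# Every stochastic stage draws its RNG seed from a single master seed plus a
# stage name, so changing the internals of one stage cannot silently shift the
# random numbers another stage sees.

#' Derive a stage-specific RNG seed from a master seed
#'
#' Hashes `(seed, stream)` into a reproducible 31-bit integer. Used by every
#' stochastic function in the package so that one master seed drives named,
#' independent substreams.
#'
#' @param seed Integer master seed.
#' @param stream Character stage name (e.g. `"simulate"`, `"rf"`).
#' @return A single integer in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(1L, "simulate")
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  # FNV-style accumulation over the stream name, folded with the master seed;
  # all arithmetic kept in double below 2^53 then reduced mod 2^31 - 1.
  h <- (abs(seed) %% 2147483647) + 1
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
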