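#' Derive a named substream seed from a master seed
#'
#' All stochastic stages of the pipeline draw their randomness from a named
#' substream of the master seed, so that adding repetitions to one stage never
#' perturbs another. The substream seed is a deterministic 31-bit hash of the
#' master seed and the stream name.
#'
#' @param seed non-negative integer master seed.
#' @param stream character scalar naming the consumer (e.g. "rarefy").
#' @return A non-negative integer seed below 2^31.
#' @export
substreamSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, !is.na(seed), seed >= 0,
            is.character(stream), length(stream) == 1L)
  # FNV-1a style accumulation in double precision (exact below 2^53)
  h <- 2166136261
  mix <- function(h, byte) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(byte))
    (h * 16777619) %% 2^31
  }
  for (b in utf8ToInt(stream)) h <- mix(h, b)
  for (b in c(seed %% 256, seed %/% 256 %% 256, seed %/% 65536 %% 256,
              seed %/% 16777216 %% 256)) h <- mix(h, b)
  as.integer(h %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded from (seed, stream),
# restoring the caller's RNG state afterwards.
withSubstream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, stream))
  expr
}
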