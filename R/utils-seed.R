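#' Derive a reproducible child seed from a master seed and a stream name
#'
#' Every stochastic stage of the pipeline draws its randomness from its own
#' named substream so that stages can be re-run independently and adding a
#' stage never perturbs the randomness of another. The child seed is a
#' deterministic 31-bit hash of the master seed and the stream label.
#'
#' @param seed Master integer seed.
#' @param key Character stream label (e.g. `"generate"`, `"elo"`).
#' @return An integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "elo")
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (ch in utf8ToInt(key)) {
    h <- (h * 131 + ch) %% m
  }
  # Lehmer step to decorrelate consecutive master seeds
  h <- (h * 48271) %% m
  as.integer(if (h == 0) 1 else h)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
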