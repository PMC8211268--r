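#' @title Deterministic substream seeds
#' @description
#' All randomness in mammosim flows from a single master seed through named
#' substreams. A substream seed is derived by hashing the master seed together
#' with a key (purpose strings, ages, ids) into a 31-bit integer, which then
#' initialises R's generator via [set.seed()]. The hash is a multiply-add
#' chain kept below 2^48 so double arithmetic is exact; the modulus is the
#' Mersenne prime 2^31 - 1, keeping every derived seed a valid R integer.
#'
#' Because substreams are keyed, not sequential, adding a scenario or a
#' purpose never shifts the draws of another: this is what makes paired
#' (common-random-number) scenario contrasts exact.
#'
#' @param seed master seed (integer-like scalar)
#' @param ... key components: character scalars or numeric scalars/vectors.
#'   Numeric components are folded at 1e-6 resolution so ages key stably.
#' @return integer seed in [1, 2^31 - 2]; vectorised over a single vector
#'   component if one is supplied.
#' @examples
#' derive_seed(1, "screen", 50)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  fold_chr <- function(h, s) {
    for (b in utf8ToInt(s)) h <- (h * 69069 + b + 1) %% m
    h
  }
  fold_num <- function(h, v) {
    v <- round(v * 1e6) %% m
    ((h * 69069) %% m + v + 1) %% m
  }
  h <- fold_num(104729, as.numeric(seed))
  for (k in list(...)) {
    if (is.character(k)) {
      for (s in k) h <- fold_chr(h, s)
    } else {
      h <- fold_num(h, as.numeric(k))
    }
  }
  # two scramble rounds so near-identical keys disperse
  h <- (h * 69069 + 12345) %% m
  h <- (h * 69069 + 12345) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a derived seed, preserving global RNG state
#'
#' @param seed derived seed (see [derive_seed()])
#' @param expr expression drawing random numbers
#' @return value of `expr`
#' @keywords internal
with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Draw n uniforms from a keyed substream
#'
#' @param n number of draws
#' @param seed master seed
#' @param ... substream key (passed to [derive_seed()])
#' @return numeric vector of uniforms in (0, 1)
#' @export
stream_runif <- function(n, seed, ...) {
  with_stream(derive_seed(seed, ...), stats::runif(n))
}
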