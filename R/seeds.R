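#' Derive a stage seed from a global seed
#'
#' Deterministically fans a single global seed out to per-stage seeds so that
#' every source of randomness in a pipeline run (phantom simulation, fold
#' assignment, weight initialisation, data order, bootstrap) gets its own
#' reproducible stream.  Labels are mixed into the seed with a
#' multiply-xor integer hash; the result always lies in [1, 2^31 - 2] so it is
#' a valid R random seed.
#'
#' @param seed integer global seed.
#' @param ... stage labels (character or integer scalars), e.g.
#'   `seed_stream(7, "train", fold = 2, init = 3)`.
#' @return An integer seed.
#' @examples
#' seed_stream(1, "phantom")
#' seed_stream(1, "train", 2, 3)
#' @export
seed_stream <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- as.double(seed) %% m
  for (lab in list(...)) {
    codes <- if (is.character(lab)) utf8ToInt(lab) else as.double(lab)
    for (cc in codes) {
      # affine mix per symbol; doubles hold exact integers below 2^53
      h <- (h * 48271 + (cc %% m) + 11) %% m
      h <- (h * 69621 + 7919) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
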