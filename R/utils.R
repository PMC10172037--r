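# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic fan-out of one master seed into per-stage child seeds,
# kept inside 32-bit integer range.
.childSeed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483629
}

# Min-max scale each column (gene) to [0, 1]; constant columns map to 0.
# Returns the scaled matrix with the ranges attached for provenance.
.minmaxScale <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
  attr(Xs, "scale.min") <- lo
  attr(Xs, "scale.range") <- rng
  Xs
}

.assertMatrix <- function(X, name = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (anyNA(X) || any(!is.finite(X)))
    stop(name, " must not contain missing or non-finite values", call. = FALSE)
  X
}
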