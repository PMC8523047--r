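# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  All stochastic steps in the package go
# through this so a single configured seed controls every random draw.
with_local_seed <- function(seed, code) {
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
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Squared Euclidean distance matrix between rows of a (n x d) and b (m x d).
pdist2 <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Direction-invariant angle in [0, pi) of the vector (dx, dy).
axis_angle <- function(dx, dy) {
  atan2(dy, dx) %% pi
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
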