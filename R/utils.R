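## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards. All stochastic functions in the
## package route their draws through this so that a single integer seed
## fully determines a run.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derive a distinct 31-bit sub-seed from a master seed and a counter.
sub_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + 1103515245 * as.double(counter) + 12345) %%
               2147483647)
}

row_norms <- function(x) sqrt(rowSums(x * x))

## n x 3 matrix coercion with validation.
as_points3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3L)
    stop(sprintf("%s must be an n x 3 matrix", what), call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop(sprintf("%s contain non-finite values", what),
                               call. = FALSE)
  dimnames(x) <- NULL
  x
}

## Squared Euclidean cross-distances between the rows of two n x 3 matrices.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

## Index of nearest row of `b` for each row of `a` (brute force, chunked so
## the distance matrix never exceeds ~32M entries).
nearest_index <- function(a, b, chunk = max(1L, floor(3.2e7 / nrow(b)))) {
  n <- nrow(a)
  out <- integer(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    out[i:j] <- max.col(-cross_dist2(a[i:j, , drop = FALSE], b), "first")
    i <- j + 1L
  }
  out
}
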