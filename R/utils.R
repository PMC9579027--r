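# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so seeded functions do not perturb global RNG flow.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Squared Euclidean cross-distance matrix, nrow(a) x nrow(b).
.crossDist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Brute-force k-nearest neighbours of each row of `query` among rows of `ref`.
# Returns list(idx = n x k matrix, dist = n x k matrix). Exact; clouds in this
# domain hold at most a few thousand nuclei so no spatial index is needed.
.knn <- function(query, ref, k) {
  k <- min(k, nrow(ref))
  d2 <- .crossDist2(query, ref)
  idx <- matrix(0L, nrow(query), k)
  dst <- matrix(0, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    o <- order(d2[i, ])[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- sqrt(d2[i, o])
  }
  list(idx = idx, dist = dst)
}

# Nearest neighbour only (vectorized, avoids the per-row sort).
.nn1 <- function(query, ref) {
  d2 <- .crossDist2(query, ref)
  idx <- max.col(-d2, ties.method = "first")
  list(idx = idx, dist = sqrt(d2[cbind(seq_len(nrow(query)), idx)]))
}

# Mean nearest-neighbour spacing of a cloud's coordinates.
.meanNNSpacing <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d2 <- .crossDist2(pts, pts)
  diag(d2) <- Inf
  mean(sqrt(apply(d2, 1, min)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
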