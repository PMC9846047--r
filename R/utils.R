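# internal helpers shared across modules

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run expr with a temporary RNG state seeded from `seed`; the caller's RNG
# stream is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic fan-out of one user seed into per-purpose sub-seeds,
# kept inside the 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(k)) %% 2147483647)
}

# Column-wise Pearson correlation of the columns of `m` with vector `y`,
# NA for constant columns instead of a warning.
.colCors <- function(m, y) {
  m <- as.matrix(m)
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- sweep(m, 2L, colMeans(m))
  sm <- sqrt(colSums(mc^2))
  out <- as.numeric(crossprod(mc, yc)) / (sm * sy)
  out[sm < 1e-300 | sy < 1e-300] <- NA_real_
  out
}
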