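# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed from a base seed and a string key, so
# that independent stages (and independent groups within a stage) draw from
# distinct but reproducible streams. Result is always in [0, 2^31 - 2].
mix_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# Row-wise Pearson correlation between matched rows of two genes x subjects
# matrices. Degenerate rows (zero variance in either region) give NA, never
# an error: constant probesets are flagged, not fatal.
row_cor <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  sa <- rowSums(ac * ac)
  sb <- rowSums(bc * bc)
  # relative tolerance: a row is degenerate when its centred sum of squares
  # is at machine-noise level for its magnitude
  tol_a <- (1e-12 * (1 + abs(rowMeans(a))))^2 * ncol(a)
  tol_b <- (1e-12 * (1 + abs(rowMeans(b))))^2 * ncol(b)
  bad <- (sa <= tol_a) | (sb <= tol_b)
  r <- rowSums(ac * bc) / sqrt(sa * sb)
  r <- pmin(1, pmax(-1, r))
  r[bad] <- NA_real_
  r
}

# Random permutation of 1..n with no fixed points (derangement), by
# rejection; acceptance probability tends to 1/e so this is cheap.
rderangement <- function(n) {
  stopifnot(n >= 2L)
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

rowQuantiles <- function(x, probs) {
  t(apply(x, 1L, stats::quantile, probs = probs, na.rm = TRUE, names = FALSE))
}

rowMedians <- function(x) {
  apply(x, 1L, stats::median, na.rm = TRUE)
}
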