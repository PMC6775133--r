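# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L) # materialize a RNG state so we can restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Smallest 5-smooth integer >= n that is divisible by `mult`.
# Used to pick FFT-friendly padded lengths.
next_fast_len <- function(n, mult = 1L) {
  n <- as.integer(ceiling(n / mult))
  is_smooth <- function(k) {
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    k == 1L
  }
  while (!is_smooth(n)) n <- n + 1L
  n * as.integer(mult)
}

# Pearson correlation with the convention that zero-variance inputs give 0
# (used for degenerate trials/templates so winner-takes-all can tie-break).
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# Row-wise Pearson correlation between two conformable matrices, zero-variance
# rows mapping to 0. Vectorized workhorse for template matching.
row_cors <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  na <- rowSums(a * a)
  nb <- rowSums(b * b)
  num <- rowSums(a * b)
  den <- sqrt(na * nb)
  out <- ifelse(den > 0, num / den, 0)
  out[!is.finite(out)] <- 0
  out
}

# Template-match scores for row-paired feature/template matrices: Pearson
# row correlations, except for one-dimensional features, where correlation
# is undefined (a scalar has no variance) and the negative absolute
# distance to the template is used instead.
match_scores <- function(feats, tpl) {
  if (ncol(feats) == 1L) {
    return(-abs(feats[, 1L] - tpl[, 1L]))
  }
  row_cors(feats, tpl)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive scalar", name), call. = FALSE)
  }
  invisible(x)
}
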