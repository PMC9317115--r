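# Internal helpers shared across the package.

# Index of unordered pair (i, j) in the condensed upper triangle of an
# F x F correlation matrix, row-major over i < j:
#   (1,2), (1,3), ..., (1,F), (2,3), ..., (F-1,F).
# Arithmetic is done in doubles: for F = 17,328 the largest index is
# 150,121,128, well within exact double range but past .Machine$integer.max/14.
pair_index <- function(i, j, n_features) {
  ii <- pmin(i, j)
  jj <- pmax(i, j)
  (ii - 1) * n_features - ii * (ii - 1) / 2 + (jj - ii)
}

# Condensed indices of every pair involving feature i, in partner order
# 1, ..., i-1, i+1, ..., F.
neighbor_indices <- function(i, n_features) {
  F <- n_features
  out <- numeric(0)
  if (i > 1) {
    k <- seq_len(i - 1)
    out <- (k - 1) * F - k * (k - 1) / 2 + (i - k)
  }
  if (i < F) {
    first <- (i - 1) * F - i * (i - 1) / 2 + 1
    out <- c(out, seq(first, first + (F - i) - 1))
  }
  out
}

# Deterministic stream-splitting: one user-facing seed fans out into
# independent sub-streams (cohort, replication, annotation, miRNA layer, ...)
# so each sub-simulation is reproducible in isolation. Kept below 2^31 - 1.
split_seed <- function(seed, stream) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + 9973 * as.numeric(stream)
  as.integer(s %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
          class = "bloodcorr_invalid_argument")
  }
  invisible(x)
}
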