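# Independent oracles used across the suite. These deliberately re-derive
# each quantity from its textbook definition, sharing no code with the
# package implementation.

# Product-moment formula evaluated directly from the sums.
naive_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# All-pairs correlation by an explicit double loop (features x samples input).
naive_all_pairs <- function(X, min_n = 3) {
  F <- nrow(X)
  r <- numeric(F * (F - 1) / 2)
  n_obs <- integer(length(r))
  k <- 0L
  for (i in seq_len(F - 1)) {
    for (j in seq(i + 1, F)) {
      k <- k + 1L
      ok <- !is.na(X[i, ]) & !is.na(X[j, ])
      n_obs[k] <- sum(ok)
      r[k] <- if (n_obs[k] >= min_n) naive_pearson(X[i, ], X[j, ]) else NA_real_
    }
  }
  list(r = r, n_obs = n_obs)
}

# Benjamini-Hochberg adjusted values straight from the step-up definition:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, clamp at 1, unsort.
bh_adjust_oracle <- function(p, m = length(p)) {
  o <- order(p)
  po <- p[o]
  k <- length(p)
  q_sorted <- vapply(seq_len(k), function(i) {
    min(po[i:k] * m / seq(i, k))
  }, numeric(1))
  q <- numeric(k)
  q[o] <- pmin(1, q_sorted)
  q
}

# BH step-up rejection set: largest i with p_(i) <= i * alpha / m rejects
# all smaller-ranked p-values.
bh_reject_oracle <- function(p, alpha, m = length(p)) {
  o <- order(p)
  i_ok <- which(p[o] <= seq_along(p) * alpha / m)
  if (length(i_ok) == 0) return(integer(0))
  sort(o[seq_len(max(i_ok))])
}

# Small planted-structure spec used by several files: one hub, a handful of
# responders, quick to build.
tiny_spec <- function(n_features = 120, n_responders = 20, loading = 0.8,
                      n_samples = 60, rng_seed = 42) {
  simulation_spec(
    n_samples = n_samples, n_features = n_features,
    hubs = list(list(hub_id = "HUB1", n_responders = n_responders,
                     loading = loading)),
    pcr_block = list(n_mirna = 5, coupling = -0.6, ct_dropout_rate = 0.1),
    replication = list(n_samples_rep = 150, feature_dropout_rate = 0.1),
    rng_seed = rng_seed)
}

# Random expression matrix fixture.
random_expr <- function(F, n, seed = 1, prefix = "F") {
  set.seed(seed)
  X <- matrix(rnorm(F * n), nrow = F,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(F)),
                              sprintf("S%03d", seq_len(n))))
  expression_matrix(X)
}

# Minimal annotation table builder.
make_annotation <- function(...) {
  tab <- tibble::tibble(...)
  for (col in c("entrez_id", "gene_symbol", "accessions", "gene_title", "go_terms")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab
}
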