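# Correlation store: the all-pairs Pearson matrix, computed blockwise and
# persisted in a compact single-file container.
#
# On-disk layout (all little-endian):
#   bytes 0-8    magic "BLOODCOR1"
#   bytes 9-12   uint32 L = length of the JSON metadata that follows
#   L bytes      UTF-8 JSON metadata (n_features, n_samples, n_pairs, min_n,
#                feature_ids, platform, dropped features, build config)
#   n_pairs * 4  float32 r, condensed upper triangle in pair_index() order
#   n_pairs * 2  uint16 n_obs, same order
# Only (r, n_obs) are stored; raw p, Bonferroni p and BH q are derived at
# query time, so the multiple-testing family can be chosen per query without
# rebuilding, and the payload stays at 6 bytes/pair (~900 MB for the full
# 17,328-feature cohort matrix of 150,121,128 pairs).

STORE_MAGIC <- "BLOODCOR1"

#' Number of unordered feature pairs
#'
#' @param n_features Number of retained features F.
#' @return F * (F - 1) / 2 as a double (exact for any realistic F).
#' @examples
#' n_pairs(17328) # 150,121,128 -- a matrix of > 150 million correlations
#' @export
n_pairs <- function(n_features) {
  as.numeric(n_features) * (as.numeric(n_features) - 1) / 2
}

#' Build the all-pairs correlation store
#'
#' Computes Pearson r for every unordered pair of retained features and
#' (optionally) persists the result. Complete-case rows (all array rows, and
#' PCR rows without missing cells) are standardised once and correlated by
#' accumulating block outer products; pairs involving a PCR row with
#' missingness fall back to pairwise-complete computation. Zero-variance
#' features are excluded with a warning before pairing, so the store never
#' holds undefined records. Pairs whose pairwise-complete count falls below
#' `min_n` are kept but flagged undetected (r stored as missing).
#'
#' @param em An `expr_matrix` (already detection-filtered; see
#'   [load_expression()]).
#' @param out_path Optional file path; when given the store is written there.
#' @param block_size Number of features per block in the outer-product
#'   accumulation (default 1024; memory use scales with `block_size^2`).
#' @param min_n Minimum pairwise-complete observations for a pair to be
#'   reported (default 20).
#' @return A `correlation_store` object (payload held in memory; also on disk
#'   when `out_path` is given).
#' @export
build_store <- function(em, out_path = NULL, block_size = 1024, min_n = 20) {
  stopifnot(inherits(em, "expr_matrix"))
  assert_scalar_number(min_n, "min_n", lower = 3)
  n_samples <- ncol(em$values)
  if (n_samples < min_n) {
    abort("fewer samples than `min_n`", class = "bloodcorr_invalid_argument")
  }

  sds <- apply(em$values, 1, stats::sd, na.rm = TRUE)
  n_obs_feat <- rowSums(!is.na(em$values))
  degenerate <- is.na(sds) | sds == 0 | n_obs_feat < 2
  if (any(degenerate)) {
    warn(paste0("excluding ", sum(degenerate), " zero-variance feature(s): ",
                paste(head(rownames(em$values)[degenerate], 5), collapse = ", ")))
    kept <- expression_matrix(em$values[!degenerate, , drop = FALSE],
                              em$platform[!degenerate])
  } else {
    kept <- em
  }
  em_platform <- kept$platform
  if (nrow(kept$values) < 2) {
    abort("need at least 2 retained features", class = "bloodcorr_invalid_argument")
  }
  ap <- all_pairs_r(kept, block_size = block_size, min_n = min_n)
  F <- nrow(kept$values)
  P <- n_pairs(F)

  # float32 storage precision: round-trip now so the in-memory store matches
  # the on-disk payload bit for bit (|delta r| <= 6e-8, negligible for p).
  r_all <- float32_roundtrip(ap$r)

  report <- attr(em, "detection_report")
  meta <- list(
    format = "bloodcorr-store",
    format_version = 1L,
    n_features = F,
    n_samples = n_samples,
    n_pairs = P,
    min_n = min_n,
    feature_ids = rownames(kept$values),
    platform = unname(em_platform),
    dropped_zero_variance = if (any(degenerate)) rownames(em$values)[degenerate] else character(0),
    dropped_detection = if (!is.null(report)) report$feature_id[!report$retained] else character(0),
    build = list(block_size = block_size)
  )
  store <- structure(list(meta = meta, feature_ids = meta$feature_ids,
                          r = r_all, n_obs = as.integer(ap$n_obs),
                          path = out_path),
                     class = "correlation_store")
  if (!is.null(out_path)) write_store(store, out_path)
  store
}

#' All-pairs Pearson correlations at full precision
#'
#' The computational core of [build_store()]: every unordered feature pair's
#' (r, n_obs), as double precision, in condensed upper-triangle order
#' (pair (i, j) of F features at index `(i-1)*F - i*(i-1)/2 + (j-i)`).
#' Complete rows go through the blockwise standardised outer-product path;
#' rows with missing cells fall back to pairwise-complete computation. Pairs
#' with fewer than `min_n` complete observations get `NA` r. Assumes no
#' zero-variance features (callers filter those first).
#'
#' @inheritParams build_store
#' @return List with numeric vector `r` and integer vector `n_obs`, each of
#'   length F(F-1)/2.
#' @export
all_pairs_r <- function(em, block_size = 1024, min_n = 20) {
  stopifnot(inherits(em, "expr_matrix"))
  assert_scalar_number(block_size, "block_size", lower = 1)
  X <- em$values
  n_samples <- ncol(X)
  F <- nrow(X)
  P <- n_pairs(F)
  r_all <- rep(NA_real_, P)
  n_all <- rep(n_samples, P)

  complete <- !apply(is.na(X), 1, any)
  ci <- which(complete)
  if (length(ci) > 1) {
    # standardise so that tcrossprod of blocks yields r directly
    S <- X[ci, , drop = FALSE]
    S <- S - rowMeans(S)
    S <- S / sqrt(rowSums(S^2))
    nb <- length(ci)
    starts <- seq(1, nb, by = block_size)
    for (a in starts) {
      ia <- a:min(a + block_size - 1, nb)
      for (b in starts[starts >= a]) {
        ib <- b:min(b + block_size - 1, nb)
        M <- tcrossprod(S[ia, , drop = FALSE], S[ib, , drop = FALSE])
        gi <- ci[ia]; gj <- ci[ib]
        keep <- outer(gi, gj, `<`)
        if (any(keep)) {
          idx <- pair_index(outer(gi, gj, function(i, j) i)[keep],
                            outer(gi, gj, function(i, j) j)[keep], F)
          r_all[idx] <- M[keep]
        }
      }
    }
  }

  mi <- which(!complete)
  if (length(mi) > 0) {
    # pairwise-complete fallback for rows with missing cells
    Rm <- suppressWarnings(
      stats::cor(t(X[mi, , drop = FALSE]), t(X), use = "pairwise.complete.obs"))
    obs <- !is.na(X)
    Nm <- obs[mi, , drop = FALSE] %*% t(obs)
    for (a in seq_along(mi)) {
      i <- mi[a]
      j <- seq_len(F)[-i]
      idx <- pair_index(pmin(i, j), pmax(i, j), F)
      rr <- Rm[a, j]
      nn <- Nm[a, j]
      rr[nn < min_n] <- NA_real_ # undetected pair
      r_all[idx] <- rr
      n_all[idx] <- nn
    }
  }

  list(r = r_all, n_obs = as.integer(n_all))
}

float32_roundtrip <- function(x) {
  raw <- writeBin(x, raw(), size = 4, endian = "little")
  y <- readBin(raw, numeric(), length(x), size = 4, endian = "little")
  y[is.nan(y)] <- NA_real_
  y
}

#' Write a correlation store to its single-file container
#'
#' @param store A `correlation_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_store <- function(store, path) {
  stopifnot(inherits(store, "correlation_store"))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort(paste0("cannot write store: ", path),
                                            class = "bloodcorr_io_error"))
  on.exit(close(con))
  meta_json <- charToRaw(jsonlite::toJSON(store$meta, auto_unbox = TRUE,
                                          digits = NA))
  writeBin(charToRaw(STORE_MAGIC), con)
  writeBin(length(meta_json), con, size = 4, endian = "little")
  writeBin(meta_json, con)
  writeBin(store$r, con, size = 4, endian = "little")
  writeBin(store$n_obs, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a correlation store from disk
#'
#' @param path Path to a store file written by [write_store()].
#' @return A `correlation_store`.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such store file: ", path), class = "bloodcorr_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), nchar(STORE_MAGIC)))
  if (!identical(magic, STORE_MAGIC)) {
    abort("not a bloodcorr correlation store", class = "bloodcorr_io_error")
  }
  L <- readBin(con, integer(), 1, size = 4, endian = "little")
  meta <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), L)),
                             simplifyVector = TRUE)
  P <- meta$n_pairs
  r <- readBin(con, numeric(), P, size = 4, endian = "little")
  r[is.nan(r)] <- NA_real_
  n_obs <- readBin(con, integer(), P, size = 2, signed = FALSE,
                   endian = "little")
  structure(list(meta = meta, feature_ids = meta$feature_ids, r = r,
                 n_obs = n_obs, path = path),
            class = "correlation_store")
}

#' @export
print.correlation_store <- function(x, ...) {
  cat(sprintf("<correlation_store> %d features x %d samples: %s pairs (min_n = %d)\n",
              x$meta$n_features, x$meta$n_samples,
              format(x$meta$n_pairs, big.mark = ","), x$meta$min_n))
  invisible(x)
}

store_feature_index <- function(store, id, arg = "feature") {
  i <- match(id, store$feature_ids)
  if (is.na(i)) {
    if (id %in% store$meta$dropped_detection) {
      abort(sprintf("feature %s was removed at detection filtering", id),
            class = c("bloodcorr_feature_dropped", "bloodcorr_not_found"))
    }
    if (id %in% store$meta$dropped_zero_variance) {
      abort(sprintf("feature %s was excluded as zero-variance at build", id),
            class = c("bloodcorr_feature_dropped", "bloodcorr_not_found"))
    }
    abort(sprintf("feature %s is not present in the store", id),
          class = "bloodcorr_not_found")
  }
  i
}

# Corrections for a vector of raw p-values under the chosen family.
family_m <- function(store, family) {
  switch(family,
         global = store$meta$n_pairs,
         per_seed = store$meta$n_features - 1,
         abort('`family` must be "global" or "per_seed"',
               class = "bloodcorr_invalid_argument"))
}

#' Look up one correlation record
#'
#' Symmetric pair lookup: `lookup_pair(store, a, b)` and
#' `lookup_pair(store, b, a)` return the identical record, with `feature_a`
#' and `feature_b` in lexicographic order. Raw p, Bonferroni p and BH q are
#' derived on the fly from the stored (r, n_obs), so the multiple-testing
#' family can be chosen per query: `"global"` is all F(F-1)/2 stored pairs,
#' `"per_seed"` the F-1 neighbors of the pair's lexicographically first
#' feature (so the record stays symmetric in its arguments). Bonferroni
#' defaults to the global family (the whole-matrix framing); BH to the
#' per-seed family, which is also what a neighbor scan reports — a global BH
#' q is available but costs a pass over every stored pair.
#'
#' @param store A `correlation_store`.
#' @param id_a,id_b Feature IDs.
#' @param family Bonferroni family, `"global"` (default) or `"per_seed"`.
#' @param bh_family BH family, `"per_seed"` (default) or `"global"`.
#' @return One-row tibble: `feature_a`, `feature_b`, `r`, `n_obs`, `p_raw`,
#'   `p_bonferroni`, `q_bh`, `detected`.
#' @export
lookup_pair <- function(store, id_a, id_b, family = c("global", "per_seed"),
                        bh_family = c("per_seed", "global")) {
  stopifnot(inherits(store, "correlation_store"))
  family <- match.arg(family)
  bh_family <- match.arg(bh_family)
  if (identical(id_a, id_b)) {
    abort("a feature has no correlation record with itself",
          class = "bloodcorr_invalid_argument")
  }
  i <- store_feature_index(store, id_a)
  j <- store_feature_index(store, id_b)
  fa <- min(id_a, id_b)
  fb <- max(id_a, id_b)
  idx <- pair_index(i, j, store$meta$n_features)
  r <- store$r[idx]
  n_obs <- store$n_obs[idx]
  m <- family_m(store, family)
  if (is.na(r)) {
    return(tibble(feature_a = fa, feature_b = fb, r = NA_real_, n_obs = n_obs,
                  p_raw = NA_real_, p_bonferroni = NA_real_, q_bh = NA_real_,
                  detected = FALSE))
  }
  p <- correlation_pvalue(r, n_obs)
  if (bh_family == "global") {
    ok <- !is.na(store$r)
    ps <- correlation_pvalue(store$r[ok], store$n_obs[ok])
    q <- bh_rank_of(p, ps, store$meta$n_pairs)
  } else {
    seed_id <- fa # canonical seed: lexicographically first member
    si <- store_feature_index(store, seed_id)
    nidx <- neighbor_indices(si, store$meta$n_features)
    rr <- store$r[nidx]
    ok <- !is.na(rr)
    ps <- correlation_pvalue(rr[ok], store$n_obs[nidx][ok])
    q <- bh_rank_of(p, ps, store$meta$n_features - 1)
  }
  tibble(feature_a = fa, feature_b = fb, r = r, n_obs = n_obs, p_raw = p,
         p_bonferroni = bonferroni(p, m), q_bh = q, detected = TRUE)
}

# BH-adjusted value of a single p within family `ps` (p itself included in ps)
# without materialising the full adjusted vector order.
bh_rank_of <- function(p, ps, m) {
  qs <- bh_fdr(ps, m = m)
  min(qs[ps >= p - 1e-300 & ps <= p + 1e-300][1], 1)
}

#' Top-k most significant neighbors of a seed feature
#'
#' Ranks every detected neighbor of the seed by raw p ascending (ties broken
#' by larger |r|, then lexicographic partner ID), applies any annotation
#' filters, and returns the first `k`. BH q is computed over the seed's full
#' neighbor family (F - 1 tests) before filtering or truncation, so the
#' reported FDR refers to the complete neighbor scan, not the trimmed table.
#' Bonferroni p uses the `family` argument (default the global pair family,
#' matching the whole-matrix framing).
#'
#' @param store A `correlation_store`.
#' @param seed Feature ID of the seed transcript.
#' @param k Number of records to return (>= 0).
#' @param annotation Optional annotation tibble (see [load_annotation()]);
#'   required when `filters` uses annotation fields, and used to decorate the
#'   result rows.
#' @param filters Optional [query_spec()] restricting the output.
#' @param family Bonferroni family: `"global"` (all stored pairs, default) or
#'   `"per_seed"` (F - 1).
#' @return Tibble with columns `seed`, `partner`, `r`, `n_obs`, `p_raw`,
#'   `p_bonferroni`, `q_bh` (plus annotation columns when `annotation` is
#'   given), at most `k` rows, sorted by significance.
#' @export
top_neighbors <- function(store, seed, k, annotation = NULL, filters = NULL,
                          family = c("global", "per_seed")) {
  stopifnot(inherits(store, "correlation_store"))
  family <- match.arg(family)
  assert_scalar_number(k, "k", lower = 0)
  si <- store_feature_index(store, seed)
  F <- store$meta$n_features
  partners <- store$feature_ids[-si]
  nidx <- neighbor_indices(si, F)
  r <- store$r[nidx]
  n_obs <- store$n_obs[nidx]
  detected <- !is.na(r)
  p_raw <- rep(NA_real_, length(r))
  p_raw[detected] <- correlation_pvalue(r[detected], n_obs[detected])
  q_bh <- rep(NA_real_, length(r))
  q_bh[detected] <- bh_fdr(p_raw[detected], m = F - 1)
  m <- family_m(store, family)
  res <- tibble(seed = seed, partner = partners, r = r, n_obs = n_obs,
                p_raw = p_raw, p_bonferroni = bonferroni(p_raw, m),
                q_bh = q_bh)
  res <- res[detected, , drop = FALSE]
  if (!is.null(annotation)) {
    ann <- annotation[match(res$partner, annotation$probe_set_id),
                      setdiff(names(annotation), "probe_set_id"), drop = FALSE]
    res <- dplyr::bind_cols(res, ann)
  }
  if (!is.null(filters)) {
    res <- apply_filters(res, annotation, filters)
  }
  ord <- order(res$p_raw, -abs(res$r), res$partner, method = "radix")
  res <- res[ord, , drop = FALSE]
  head(res, k)
}
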