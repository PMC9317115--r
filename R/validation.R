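#' Binding-site enrichment of a seed's top correlates vs. a random-gene
#' baseline
#'
#' Takes the `k` transcripts most significantly correlated with a seed,
#' deduplicates them to gene level, and measures the fraction carrying a
#' given annotation (e.g. a transcription-factor binding element registered
#' by ChIP). The baseline is resampling-based: `n_resamples` independent
#' draws of `k` genes without replacement from the detected-gene universe
#' (seed excluded), summarised as mean and SD, with an empirical one-sided
#' p-value `(1 + #draws >= observed) / (n_resamples + 1)` that can never be
#' exactly zero.
#'
#' @param store A `correlation_store`.
#' @param seed Seed feature ID.
#' @param k Number of top correlates (default 200).
#' @param annotated_set Character vector of annotated gene IDs.
#' @param universe Character vector of gene IDs to draw the baseline from;
#'   defaults to every feature in the store.
#' @param n_resamples Number of random draws R (default 1000).
#' @param rng_seed Integer seed for the draws.
#' @param annotation Optional annotation tibble; when given, top-k partners
#'   are mapped to gene symbols before intersecting with `annotated_set`.
#' @return An `enrichment_result` object.
#' @export
topk_binding_enrichment <- function(store, seed, k = 200, annotated_set,
                                    universe = NULL, n_resamples = 1000,
                                    rng_seed = 1L, annotation = NULL) {
  assert_scalar_number(k, "k", lower = 1)
  assert_scalar_number(n_resamples, "n_resamples", lower = 1)
  universe <- universe %||% store$feature_ids
  universe <- setdiff(unique(universe), seed)
  if (k > length(universe)) {
    abort("`k` exceeds the universe size", class = "bloodcorr_invalid_argument")
  }
  top <- top_neighbors(store, seed, k = k)
  genes <- top$partner
  if (!is.null(annotation)) {
    sym <- annotation$gene_symbol[match(genes, annotation$probe_set_id)]
    genes <- ifelse(is.na(sym) | !nzchar(sym), genes, sym)
  }
  genes <- unique(genes)
  n_annot <- sum(genes %in% annotated_set)
  frac <- n_annot / k
  set.seed(rng_seed)
  draws <- purrr::map_dbl(seq_len(n_resamples), function(i) {
    sum(sample(universe, k) %in% annotated_set) / k
  })
  structure(list(seed = seed, k = k, n_topk_annotated = n_annot,
                 fraction_annotated = frac,
                 baseline_mean = mean(draws),
                 baseline_sd = stats::sd(draws),
                 n_resamples = n_resamples,
                 empirical_p = (1 + sum(draws >= frac)) / (n_resamples + 1),
                 baseline_fractions = draws),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> seed %s: %d/%d (%.1f%%) top correlates annotated\n",
              x$seed, x$n_topk_annotated, x$k, 100 * x$fraction_annotated))
  cat(sprintf("  random-gene baseline: %.1f%% (SD = %.1f%%) over %d draws; empirical p = %.4g\n",
              100 * x$baseline_mean, 100 * x$baseline_sd, x$n_resamples,
              x$empirical_p))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(draw = seq_len(x$n_resamples), baseline_fraction = x$baseline_fractions)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(seed = x$seed, k = x$k, n_topk_annotated = x$n_topk_annotated,
         fraction_annotated = x$fraction_annotated,
         baseline_mean = x$baseline_mean, baseline_sd = x$baseline_sd,
         n_resamples = x$n_resamples, empirical_p = x$empirical_p)
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$baseline_fraction)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$fraction_annotated,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "annotated fraction of k random genes",
      y = "draws",
      title = sprintf("Top-%d binding-site enrichment for %s",
                      object$k, object$seed),
      subtitle = sprintf("observed %.1f%% vs baseline %.1f%% (SD %.1f%%), empirical p = %.3g",
                         100 * object$fraction_annotated,
                         100 * object$baseline_mean,
                         100 * object$baseline_sd, object$empirical_p))
}

#' Replicate discovery associations in a second cohort
#'
#' Recomputes each carried-forward pair in a replication expression matrix,
#' Bonferroni-corrects over the carried-forward family, and classifies every
#' pair as `significant`, `nonsignificant` or `undetected` (either member
#' absent from the replication matrix, or too few pairwise-complete
#' observations). The three counts always sum to the number of discovery
#' pairs.
#'
#' @param discovery_pairs Data frame with columns `seed` and `partner`
#'   (optionally `discovery_r`, carried into the per-pair table).
#' @param replication An `expr_matrix` for the replication cohort.
#' @param alpha Significance level after correction (default 0.05).
#' @param family_size Bonferroni family size; defaults to the number of
#'   tested pairs and must be at least that.
#' @param min_n Minimum pairwise-complete observations (default 20).
#' @return A `replication_result` object.
#' @export
replicate_associations <- function(discovery_pairs, replication, alpha = 0.05,
                                   family_size = NULL, min_n = 20) {
  stopifnot(inherits(replication, "expr_matrix"))
  assert_scalar_number(alpha, "alpha", lower = 1e-300, upper = 1 - 1e-12)
  discovery_pairs <- as_tibble(discovery_pairs)
  if (nrow(discovery_pairs) == 0) {
    abort("empty discovery pair list", class = "bloodcorr_invalid_argument")
  }
  stopifnot(all(c("seed", "partner") %in% names(discovery_pairs)))
  m <- family_size %||% nrow(discovery_pairs)
  if (m < nrow(discovery_pairs)) {
    abort("family_size smaller than the number of tested pairs",
          class = "bloodcorr_invalid_argument")
  }
  ids <- feature_ids(replication)
  rows <- purrr::pmap_dfr(
    list(discovery_pairs$seed, discovery_pairs$partner),
    function(a, b) {
      if (!(a %in% ids) || !(b %in% ids)) {
        return(tibble(replication_r = NA_real_, n_obs = NA_integer_,
                      p_raw = NA_real_, p_bonferroni = NA_real_,
                      status = "undetected"))
      }
      ps <- pearson_r(replication$values[a, ], replication$values[b, ],
                      min_n = min_n)
      if (!ps$detected) {
        return(tibble(replication_r = NA_real_, n_obs = ps$n_obs,
                      p_raw = NA_real_, p_bonferroni = NA_real_,
                      status = "undetected"))
      }
      pb <- bonferroni(ps$p_raw, m)
      tibble(replication_r = ps$r, n_obs = ps$n_obs, p_raw = ps$p_raw,
             p_bonferroni = pb,
             status = if (pb <= alpha) "significant" else "nonsignificant")
    })
  tab <- dplyr::bind_cols(discovery_pairs, rows)
  counts <- table(factor(tab$status,
                         levels = c("significant", "nonsignificant", "undetected")))
  res <- structure(list(n_discovery = nrow(tab),
                        n_significant = unname(counts[["significant"]]),
                        n_nonsignificant = unname(counts[["nonsignificant"]]),
                        n_undetected = unname(counts[["undetected"]]),
                        alpha = alpha, family_size = m, pairs = tab),
                   class = "replication_result")
  stopifnot(res$n_discovery ==
              res$n_significant + res$n_nonsignificant + res$n_undetected)
  res
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("<replication_result> %d associations carried forward: %d reached significance, %d did not, %d undetected\n",
              x$n_discovery, x$n_significant, x$n_nonsignificant,
              x$n_undetected))
  cat(sprintf("  Bonferroni over m = %d at alpha = %g\n", x$family_size, x$alpha))
  invisible(x)
}

#' @export
tidy.replication_result <- function(x, ...) x$pairs

#' @export
glance.replication_result <- function(x, ...) {
  tibble(n_discovery = x$n_discovery, n_significant = x$n_significant,
         n_nonsignificant = x$n_nonsignificant, n_undetected = x$n_undetected,
         alpha = x$alpha, family_size = x$family_size)
}

#' @export
autoplot.replication_result <- function(object, ...) {
  tab <- tidy(object)
  if ("discovery_r" %in% names(tab)) {
    ggplot2::ggplot(tab, ggplot2::aes(x = .data$discovery_r,
                                      y = .data$replication_r,
                                      colour = .data$status)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
      ggplot2::labs(x = "discovery r", y = "replication r",
                    title = "Discovery vs. replication correlation")
  } else {
    counts <- dplyr::count(tab, .data$status)
    ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(x = NULL, y = "pairs", title = "Replication accounting")
  }
}

#' Recall of curated miRNA-target pairs at nominal significance
#'
#' Checks, for a list of experimentally supported miRNA-mRNA interactions,
#' how many are detected in the correlation store (both members retained)
#' and how many of the detected pairs reach nominal (uncorrected)
#' significance; the anti-correlated subset (r < 0, the direction expected
#' for miRNA-mediated mRNA decay) is reported separately.
#'
#' @param store A `correlation_store` built over a matrix containing the
#'   miRNA PCR layer.
#' @param pairs Data frame with columns `mirna_id` and `target_id`
#'   (duplicate pairs are dropped).
#' @param alpha Nominal significance level (default 0.05).
#' @return A `mirna_recall` object.
#' @export
mirna_target_recall <- function(store, pairs, alpha = 0.05) {
  stopifnot(inherits(store, "correlation_store"))
  assert_scalar_number(alpha, "alpha", lower = 1e-300, upper = 1 - 1e-12)
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    abort("empty miRNA-target pair set", class = "bloodcorr_invalid_argument")
  }
  stopifnot(all(c("mirna_id", "target_id") %in% names(pairs)))
  pairs <- dplyr::distinct(pairs, .data$mirna_id, .data$target_id)
  rows <- purrr::pmap_dfr(list(pairs$mirna_id, pairs$target_id),
    function(a, b) {
      if (!(a %in% store$feature_ids) || !(b %in% store$feature_ids)) {
        return(tibble(r = NA_real_, n_obs = NA_integer_, p_raw = NA_real_,
                      detected = FALSE))
      }
      rec <- lookup_pair(store, a, b)
      tibble(r = rec$r, n_obs = rec$n_obs, p_raw = rec$p_raw,
             detected = rec$detected)
    })
  tab <- dplyr::bind_cols(pairs, rows)
  det <- tab[tab$detected, , drop = FALSE]
  n_det <- nrow(det)
  n_nom <- sum(det$p_raw < alpha)
  neg <- det[det$r < 0, , drop = FALSE]
  structure(list(n_pairs_input = nrow(tab),
                 n_detected = n_det,
                 n_nominal = n_nom,
                 fraction_nominal = if (n_det > 0) n_nom / n_det else NA_real_,
                 n_negative = nrow(neg),
                 n_nominal_negative = sum(neg$p_raw < alpha),
                 fraction_nominal_negative =
                   if (nrow(neg) > 0) sum(neg$p_raw < alpha) / nrow(neg) else NA_real_,
                 alpha = alpha, pairs = tab),
            class = "mirna_recall")
}

#' @export
print.mirna_recall <- function(x, ...) {
  cat(sprintf("<mirna_recall> %d curated pairs: %d reached detection level, %d (%.0f%%) nominally significant at p < %g\n",
              x$n_pairs_input, x$n_detected, x$n_nominal,
              100 * (x$fraction_nominal %||% NA), x$alpha))
  cat(sprintf("  anti-correlated subset: %d pairs, %d nominally significant\n",
              x$n_negative, x$n_nominal_negative))
  invisible(x)
}

#' @export
tidy.mirna_recall <- function(x, ...) x$pairs

#' @export
glance.mirna_recall <- function(x, ...) {
  tibble(n_pairs_input = x$n_pairs_input, n_detected = x$n_detected,
         n_nominal = x$n_nominal, fraction_nominal = x$fraction_nominal,
         n_negative = x$n_negative,
         n_nominal_negative = x$n_nominal_negative,
         fraction_nominal_negative = x$fraction_nominal_negative,
         alpha = x$alpha)
}

#' Read a gene-set file (one gene ID per line, `#` comments allowed)
#'
#' @param path File path.
#' @return Character vector of gene IDs.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a two-column pair list TSV
#'
#' Accepts files with or without a header row; a first row whose fields look
#' like column names (`id_a`, `seed`, `mirna_id`, ...) is treated as a
#' header. `#` comment lines are skipped.
#'
#' @param path File path.
#' @param col_names Names for the two columns in the returned tibble.
#' @return Tibble with two character columns.
#' @export
read_pair_list <- function(path, col_names = c("id_a", "id_b")) {
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) < 2) {
    abort("pair list must have two tab-separated columns",
          class = "bloodcorr_parse_error")
  }
  headerish <- c("id_a", "id_b", "seed", "partner", "mirna_id", "target_id",
                 "feature_a", "feature_b")
  if (tolower(tab[[1]][1]) %in% headerish) tab <- tab[-1, , drop = FALSE]
  setNames(tab[, 1:2], col_names)
}
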