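# One small planted-structure store shared by the enrichment / recall tests.
local_store <- local({
  spec <- tiny_spec(n_features = 300, n_responders = 30, loading = 0.8,
                    n_samples = 105, rng_seed = 99)
  sim <- simulate_cohort(spec)
  full <- simulate_mirna_layer(spec, sim)
  list(spec = spec, sim = sim, full = full,
       store = build_store(full$expression, min_n = 20))
})

test_that("enrichment saturates when every gene is annotated and vanishes when none is", {
  st <- local_store$store
  all_genes <- st$feature_ids
  res <- topk_binding_enrichment(st, "HUB1", k = 20, annotated_set = all_genes,
                                 universe = all_genes, n_resamples = 50,
                                 rng_seed = 1)
  expect_equal(res$fraction_annotated, 1)
  expect_equal(res$baseline_mean, 1)
  expect_equal(res$baseline_sd, 0)
  expect_equal(res$empirical_p, 1)

  res0 <- topk_binding_enrichment(st, "HUB1", k = 20,
                                  annotated_set = c("NOT_A", "NOT_B"),
                                  universe = all_genes, n_resamples = 50,
                                  rng_seed = 1)
  expect_equal(res0$fraction_annotated, 0)
  expect_equal(res0$baseline_mean, 0)
  expect_equal(res0$empirical_p, 1)
})

test_that("the resampling baseline converges to the universe annotation rate", {
  st <- local_store$store
  truth <- local_store$sim$truth
  annotated <- simulate_annotation(truth, enriched_rate = 0.91,
                                   background_rate = 0.483, rng_seed = 5)
  res <- topk_binding_enrichment(st, "HUB1", k = 30, annotated_set = annotated,
                                 n_resamples = 2000, rng_seed = 17)
  universe <- setdiff(st$feature_ids, "HUB1")
  target <- length(intersect(annotated, universe)) / length(universe)
  expect_lt(abs(res$baseline_mean - target),
            3 * res$baseline_sd / sqrt(res$n_resamples) + 1e-12)
  expect_gt(res$empirical_p, 0)
  expect_lte(res$empirical_p, 1)
  # the planted regulon is detected as enriched over the baseline
  expect_gt(res$fraction_annotated, res$baseline_mean + 2 * res$baseline_sd)
})

test_that("the empirical p-value is super-uniform under a null annotation", {
  st <- local_store$store
  universe <- st$feature_ids
  set.seed(404)
  hits <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    # annotation independent of the correlation structure: the observed
    # top-k fraction is exchangeable with the random draws
    annotated <- sample(universe, 150)
    p <- topk_binding_enrichment(st, "G00250", k = 20,
                                 annotated_set = annotated,
                                 n_resamples = 99,
                                 rng_seed = i)$empirical_p
    expect_gt(p, 0)
    if (p <= 0.1) hits <- hits + 1L
  }
  # P(hits > 15) under Binomial(60, 0.1) is < 1e-3
  expect_lte(hits, 15)
})

test_that("k larger than the universe is rejected", {
  st <- local_store$store
  expect_error(topk_binding_enrichment(st, "HUB1", k = 1000,
                                       annotated_set = "x",
                                       universe = st$feature_ids[1:10]),
               class = "bloodcorr_invalid_argument")
})

test_that("a cohort replicates itself", {
  sim <- local_store$sim
  pairs <- tibble::tibble(seed = "HUB1",
                          partner = sim$truth$planted_pairs$responder_id)
  res <- replicate_associations(pairs, sim$expression, alpha = 0.05)
  expect_equal(res$n_discovery, nrow(pairs))
  expect_equal(res$n_undetected, 0)
  expect_equal(res$n_significant, res$n_discovery) # loading 0.8 at n = 105
  expect_equal(res$n_discovery,
               res$n_significant + res$n_nonsignificant + res$n_undetected)
})

test_that("replication accounting classifies absent partners and weak pairs", {
  set.seed(2)
  n <- 400
  F <- 220
  ids <- c("SEED", sprintf("P%03d", 1:(F - 1)))
  z <- rnorm(n)
  X <- matrix(rnorm(F * n), nrow = F, dimnames = list(ids, paste0("S", 1:n)))
  X["SEED", ] <- z
  strong <- sprintf("P%03d", 1:180) # correlate with the seed
  weak <- sprintf("P%03d", 181:186) # independent noise: not significant
  absent <- sprintf("P%03d", 187:200) # dropped from the replication platform
  X[strong, ] <- 0.8 * matrix(z, length(strong), n, byrow = TRUE) +
    0.6 * X[strong, ]
  em <- expression_matrix(X[setdiff(ids, absent), ], "array")
  pairs <- tibble::tibble(seed = "SEED",
                          partner = c(strong, weak, absent),
                          discovery_r = 0.8)
  res <- replicate_associations(pairs, em, alpha = 0.05)
  expect_equal(res$n_discovery, 200)
  expect_equal(res$n_undetected, 14)
  expect_equal(res$n_significant, 180)
  expect_equal(res$n_nonsignificant, 6)
  tab <- tidy(res)
  expect_equal(nrow(tab), 200)
  expect_true(all(tab$status[tab$partner %in% absent] == "undetected"))
  g <- glance(res)
  expect_equal(g$n_significant + g$n_nonsignificant + g$n_undetected,
               g$n_discovery)
})

test_that("replication rejects degenerate inputs", {
  em <- random_expr(5, 25)
  expect_error(replicate_associations(tibble::tibble(seed = character(),
                                                     partner = character()),
                                      em),
               class = "bloodcorr_invalid_argument")
  expect_error(replicate_associations(tibble::tibble(seed = "F001",
                                                     partner = c("F002", "F003")),
                                      em, family_size = 1),
               class = "bloodcorr_invalid_argument")
})

test_that("miRNA-target recall accounts for detection and nominal significance", {
  st <- local_store$store
  full <- local_store$full
  pairs <- full$mirna_pairs
  # add pairs whose members never existed
  pairs_plus <- dplyr::bind_rows(
    pairs[c("mirna_id", "target_id")],
    tibble::tibble(mirna_id = c("MIRX", "MIR001"),
                   target_id = c("G00010", "GHOST")))
  res <- mirna_target_recall(st, pairs_plus, alpha = 0.05)
  expect_equal(res$n_pairs_input, nrow(pairs) + 2)
  expect_lte(res$n_detected, nrow(pairs))
  expect_gte(res$fraction_nominal, 0)
  expect_lte(res$fraction_nominal, 1)
  expect_equal(res$n_nominal / res$n_detected, res$fraction_nominal)
  # planted coupling is negative: the anti-correlated subset carries the signal
  expect_gte(res$n_negative, res$n_detected / 2)

  # invariant to pair input order
  perm <- sample(nrow(pairs_plus))
  res2 <- mirna_target_recall(st, pairs_plus[perm, ], alpha = 0.05)
  expect_equal(glance(res2)[names(glance(res2)) != "alpha"],
               glance(res)[names(glance(res)) != "alpha"])
})

test_that("recall with no detectable pair reports undefined fractions", {
  st <- local_store$store
  res <- mirna_target_recall(st, tibble::tibble(mirna_id = "NOPE1",
                                                target_id = "NOPE2"))
  expect_equal(res$n_detected, 0)
  expect_true(is.na(res$fraction_nominal))
})

test_that("gene-set and pair-list files parse with comments and headers", {
  gs <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# curated set", "CREB1", "GATA1", "", "NR3C1"), gs)
  expect_equal(read_gene_set(gs), c("CREB1", "GATA1", "NR3C1"))

  pl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\ttarget_id", "MIR1\tG1", "MIR2\tG2"), pl)
  tab <- read_pair_list(pl, col_names = c("mirna_id", "target_id"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mirna_id, c("MIR1", "MIR2"))

  pl2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("MIR1\tG1", "MIR2\tG2"), pl2)
  expect_equal(nrow(read_pair_list(pl2)), 2)
})
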