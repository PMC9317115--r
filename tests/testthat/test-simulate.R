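test_that("simulation is deterministic given the seed and splits streams", {
  spec <- tiny_spec(rng_seed = 11)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$expression$values, b$expression$values)

  # replication uses an independent stream: same structure, fresh samples
  r1 <- simulate_replication(spec, a$truth)
  r2 <- simulate_replication(spec, a$truth)
  expect_identical(r1$values, r2$values)
  expect_false(any(dim(r1)[2] == dim(a$expression)[2] &&
                     isTRUE(all.equal(r1$values[1, 1], a$expression$values[1, 1]))))

  c2 <- simulate_cohort(tiny_spec(rng_seed = 12))
  expect_false(identical(a$expression$values, c2$expression$values))
})

test_that("zero loading makes responders independent of the hub", {
  spec <- tiny_spec(n_features = 100, n_responders = 40, loading = 0,
                    n_samples = 105, rng_seed = 21)
  sim <- simulate_cohort(spec)
  X <- sim$expression$values
  r <- as.vector(cor(X["HUB1", ], t(X[sim$truth$planted_pairs$responder_id, ])))
  # each null r has SD ~ 1/sqrt(n-1) ~ 0.098; the mean of 40 is ~ N(0, 0.0155)
  expect_lt(abs(mean(r)), 3 * (1 / sqrt(104)) / sqrt(40) + 1e-12)
  expect_lt(max(abs(r)), 0.5)
})

test_that("planted hub-responder correlations centre on the loading", {
  spec <- tiny_spec(n_features = 250, n_responders = 200, loading = 0.8,
                    n_samples = 105, rng_seed = 31)
  sim <- simulate_cohort(spec)
  X <- sim$expression$values
  r <- as.vector(cor(X["HUB1", ], t(X[sim$truth$planted_pairs$responder_id, ])))
  # tolerance: 3 x the sampling SD of one r at n = 105 (Fisher-based
  # approximation (1 - rho^2) / sqrt(n - 3)); responders share the hub
  # factor, so averaging over them does not shrink the error by sqrt(200)
  expect_lt(abs(mean(r) - 0.8), 3 * (1 - 0.8^2) / sqrt(105 - 3))
})

test_that("simulated array features have unit population variance", {
  spec <- tiny_spec(n_features = 1000, n_responders = 300, loading = 0.8,
                    n_samples = 105, rng_seed = 41)
  sim <- simulate_cohort(spec)
  v <- apply(sim$expression$values, 1, var)
  # each sample variance has SD ~ sqrt(2/104) ~ 0.139; the 300 responders
  # share the hub factor, so the mean's SD is dominated by the common
  # lambda^2 * var(z-hat) term (~ 0.3 * 0.64 * 0.139 ~ 0.027), not by 1/sqrt(1000)
  expect_lt(abs(mean(v) - 1), 3 * 0.03)
  expect_gt(min(v), 0.4)
  expect_lt(max(v), 2)
})

test_that("replication dropout removes the expected share of features", {
  spec0 <- tiny_spec(rng_seed = 51)
  spec0$replication$feature_dropout_rate <- 0
  full_set <- simulate_replication(spec0, simulate_cohort(spec0)$truth)
  expect_setequal(feature_ids(full_set),
                  simulate_cohort(spec0)$truth$roles$feature_id)

  spec <- tiny_spec(n_features = 500, n_responders = 50, rng_seed = 52)
  spec$replication$feature_dropout_rate <- 0.07
  truth <- simulate_cohort(spec)$truth
  rep_em <- simulate_replication(spec, truth)
  n_dropped <- 500 - nrow(rep_em$values)
  # Binomial(499, 0.07): mean 34.9, SD 5.7; hubs never drop
  expect_gt(n_dropped, 35 - 4 * 5.7)
  expect_lt(n_dropped, 35 + 4 * 5.7)
  expect_true("HUB1" %in% feature_ids(rep_em))
})

test_that("replication power at the cohort scale is near-total for planted pairs", {
  spec <- tiny_spec(n_features = 80, n_responders = 20, loading = 0.3,
                    rng_seed = 61)
  spec$replication <- list(n_samples_rep = 1204, feature_dropout_rate = 0)
  sim <- simulate_cohort(spec)
  rep_em <- simulate_replication(spec, sim$truth)
  pairs <- tibble::tibble(seed = "HUB1",
                          partner = sim$truth$planted_pairs$responder_id)
  res <- replicate_associations(pairs, rep_em, alpha = 0.05)
  # analytic power of the r-to-t test at rho = 0.3, n = 1204, Bonferroni m=20
  # is > 0.9999; all 20 pairs should replicate
  expect_equal(res$n_significant, 20)
})

test_that("annotation rates follow feature roles", {
  spec <- tiny_spec(n_features = 2000, n_responders = 400, rng_seed = 71)
  truth <- simulate_cohort(spec)$truth
  ann <- simulate_annotation(truth, enriched_rate = 0.91,
                             background_rate = 0.483, rng_seed = 72)
  resp <- truth$roles$feature_id[truth$roles$role == "responder"]
  bg <- truth$roles$feature_id[truth$roles$role == "background"]
  rate_resp <- mean(resp %in% ann)
  rate_bg <- mean(bg %in% ann)
  expect_lt(abs(rate_resp - 0.91), 4 * sqrt(0.91 * 0.09 / 400))
  expect_lt(abs(rate_bg - 0.483), 4 * sqrt(0.483 * 0.517 / length(bg)))

  # degenerate rates
  expect_length(setdiff(simulate_annotation(truth, 0.5, 0, rng_seed = 3), resp), 0)
  expect_length(simulate_annotation(truth, 0, 0, rng_seed = 3), 0)
})

test_that("the miRNA layer couples negatively to its targets on the inverse-Ct scale", {
  spec <- tiny_spec(n_features = 150, n_responders = 30, rng_seed = 81)
  spec$pcr_block <- list(n_mirna = 8, coupling = -0.6, ct_dropout_rate = 0.05)
  full <- simulate_mirna_layer(spec, simulate_cohort(spec))
  X <- full$expression$values
  r <- purrr::map2_dbl(full$mirna_pairs$mirna_id, full$mirna_pairs$target_id,
                       function(a, b) pearson_r(X[a, ], X[b, ], min_n = 20)$r)
  expect_true(all(r < 0))
  expect_lt(abs(mean(r) + 0.6), 0.15)
  # stored values are inverse-Ct: back on the Ct scale they live in [18, 36]
  ct <- -X[full$mirna_pairs$mirna_id[1], ]
  expect_true(all(is.na(ct) | (ct >= 18 & ct <= 36)))

  # zero coupling: miRNA-target correlation centred on zero
  spec0 <- tiny_spec(n_features = 150, n_responders = 30, rng_seed = 82)
  spec0$pcr_block <- list(n_mirna = 8, coupling = 0, ct_dropout_rate = 0)
  full0 <- simulate_mirna_layer(spec0, simulate_cohort(spec0))
  X0 <- full0$expression$values
  r0 <- purrr::map2_dbl(full0$mirna_pairs$mirna_id, full0$mirna_pairs$target_id,
                        function(a, b) pearson_r(X0[a, ], X0[b, ], min_n = 20)$r)
  expect_lt(max(abs(r0)), 0.45)

  # total dropout: features become all-missing and fail detection
  spec1 <- tiny_spec(n_features = 50, n_responders = 10, rng_seed = 83)
  spec1$pcr_block <- list(n_mirna = 3, coupling = -0.5, ct_dropout_rate = 1)
  full1 <- simulate_mirna_layer(spec1, simulate_cohort(spec1))
  det <- detect_features(full1$expression)
  expect_false(any(det$retained[det$platform == "pcr"]))
})

test_that("an invalid spec is rejected", {
  expect_error(simulation_spec(n_features = 100,
                               hubs = list(list(hub_id = "H", n_responders = 99,
                                                loading = 0.5))),
               class = "bloodcorr_invalid_argument")
  expect_error(simulation_spec(pcr_block = list(n_mirna = 2, coupling = 0.3,
                                                ct_dropout_rate = 0)))
})

test_that("a simulated study round-trips through its files", {
  spec <- tiny_spec(n_features = 60, n_responders = 10, n_samples = 30,
                    rng_seed = 91)
  spec$replication <- list(n_samples_rep = 40, feature_dropout_rate = 0.1)
  dir <- withr::local_tempdir()
  paths <- write_simulated_study(spec, dir)
  expect_true(all(file.exists(unlist(paths))))

  em <- load_expression(paths$expression, apply_detection = FALSE)
  expect_equal(sum(em$platform == "pcr"), 5)
  ann <- load_annotation(paths$annotation)
  expect_equal(nrow(ann), 65)
  expect_match(ann$gene_title[ann$probe_set_id == "HUB1"], "transcription")
  gs <- read_gene_set(paths$gene_set)
  expect_gt(length(gs), 0)
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(length(truth$roles$feature_id), 65)
})
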