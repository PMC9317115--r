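# Synthetic cohorts with planted hub-responder correlation structure.
#
# Generative model: each hub h carries a latent factor z_h ~ N(0, 1) per
# sample; the hub transcript reports that factor directly, and each of its
# responders is lambda * z_h + sqrt(1 - lambda^2) * eps with eps ~
# N(0, noise_sd^2). With noise_sd = 1 every array feature has population
# variance 1 and the planted hub-responder population correlation is exactly
# lambda (co-responders of the same hub correlate at lambda^2). Background
# features are independent noise. This mirrors a transcription factor driving
# a regulon in a cohort expression matrix, at the 105-sample scale of a
# typical discovery cohort, with a 1204-sample replication cohort available
# from the same structure.

#' Specify a synthetic cohort
#'
#' Defaults give the "mini" preset used throughout the test-suite: 105
#' samples, 2,000 array features of which 200 respond to one hub at loading
#' 0.8, a 10-feature miRNA PCR layer coupled negatively to its targets, a
#' background binding-site annotation rate of 0.483, and a 1,204-sample
#' replication design with 7% feature dropout.
#'
#' @param n_samples Discovery cohort size (default 105).
#' @param n_features Number of array features, hubs and responders included
#'   (default 2000; the "oslo-like" scale is 17,328).
#' @param hubs List of hubs, each `list(hub_id=, n_responders=, loading=)`
#'   with loading in (0, 1).
#' @param noise_sd Standard deviation of the idiosyncratic noise (default 1,
#'   the unit-variance calibration).
#' @param background_annotation_rate Probability that a non-responder carries
#'   the binding-site annotation (default 0.483, the random-gene rate the
#'   enrichment baseline is calibrated to).
#' @param enriched_annotation_rate Probability that a responder carries it
#'   (default 0.91).
#' @param pcr_block `list(n_mirna=, coupling=, ct_dropout_rate=)`; coupling
#'   (beta) must be <= 0 so miRNAs anti-correlate with their targets.
#' @param replication `list(n_samples_rep=, feature_dropout_rate=)`.
#' @param rng_seed Integer seed; every stream of randomness in the
#'   simulation derives from it.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_samples = 105,
                            n_features = 2000,
                            hubs = list(list(hub_id = "HUB1",
                                             n_responders = 200,
                                             loading = 0.8)),
                            noise_sd = 1,
                            background_annotation_rate = 0.483,
                            enriched_annotation_rate = 0.91,
                            pcr_block = list(n_mirna = 10, coupling = -0.6,
                                             ct_dropout_rate = 0.1),
                            replication = list(n_samples_rep = 1204,
                                               feature_dropout_rate = 0.07),
                            rng_seed = 1L) {
  assert_scalar_number(n_samples, "n_samples", lower = 3)
  assert_scalar_number(n_features, "n_features", lower = 2)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(background_annotation_rate, "background_annotation_rate", 0, 1)
  assert_scalar_number(enriched_annotation_rate, "enriched_annotation_rate", 0, 1)
  for (h in hubs) {
    stopifnot(is.character(h$hub_id), h$n_responders >= 1,
              h$loading >= 0, h$loading < 1)
  }
  total_resp <- sum(purrr::map_dbl(hubs, "n_responders"))
  if (total_resp + length(hubs) >= n_features) {
    abort("hubs + responders must number fewer than n_features",
          class = "bloodcorr_invalid_argument")
  }
  stopifnot(pcr_block$coupling <= 0,
            pcr_block$ct_dropout_rate >= 0, pcr_block$ct_dropout_rate <= 1,
            replication$feature_dropout_rate >= 0,
            replication$feature_dropout_rate < 1)
  structure(list(n_samples = n_samples, n_features = n_features, hubs = hubs,
                 noise_sd = noise_sd,
                 background_annotation_rate = background_annotation_rate,
                 enriched_annotation_rate = enriched_annotation_rate,
                 pcr_block = pcr_block, replication = replication,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_spec")
}

# Draw the array block for n samples under a spec; shared by discovery and
# replication so both cohorts carry the same planted structure.
draw_array_block <- function(spec, n_samples, truth) {
  F <- spec$n_features
  X <- matrix(rnorm(F * n_samples, sd = spec$noise_sd), nrow = F,
              dimnames = list(truth$roles$feature_id[truth$roles$platform == "array"],
                              paste0("S", seq_len(n_samples))))
  for (h in spec$hubs) {
    z <- rnorm(n_samples)
    hub_row <- match(h$hub_id, rownames(X))
    X[hub_row, ] <- z
    resp <- truth$roles$feature_id[truth$roles$role == "responder" &
                                     truth$roles$hub_id == h$hub_id]
    ri <- match(resp, rownames(X))
    lam <- h$loading
    X[ri, ] <- lam * matrix(z, nrow = length(ri), ncol = n_samples,
                            byrow = TRUE) + sqrt(1 - lam^2) * X[ri, ]
  }
  X
}

build_roles <- function(spec) {
  F <- spec$n_features
  ids <- sprintf("G%05d", seq_len(F))
  role <- rep("background", F)
  hub_of <- rep(NA_character_, F)
  pos <- 1L
  for (h in spec$hubs) {
    ids[pos] <- h$hub_id
    role[pos] <- "hub"
    hub_of[pos] <- h$hub_id
    ri <- seq(pos + 1L, pos + h$n_responders)
    role[ri] <- "responder"
    hub_of[ri] <- h$hub_id
    pos <- pos + h$n_responders + 1L
  }
  tibble(feature_id = ids, role = role, hub_id = hub_of, platform = "array")
}

#' Simulate a discovery cohort
#'
#' Generates the array layer of an expression matrix under the planted
#' hub-responder factor model, plus the ground truth needed to score
#' downstream recovery. Deterministic given `spec$rng_seed`; the miRNA PCR
#' layer is added separately by [simulate_mirna_layer()].
#'
#' @param spec A [simulation_spec()].
#' @return List with elements `expression` (an `expr_matrix`) and `truth`
#'   (list: `roles` tibble with per-feature role/hub assignment,
#'   `planted_pairs` tibble of hub-responder pairs with their population
#'   correlation, and the `spec`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  roles <- build_roles(spec)
  truth <- list(roles = roles, spec = spec)
  set.seed(split_seed(spec$rng_seed, 1L))
  X <- draw_array_block(spec, spec$n_samples, truth)
  planted <- purrr::map_dfr(spec$hubs, function(h) {
    resp <- roles$feature_id[roles$role == "responder" & roles$hub_id == h$hub_id]
    tibble(hub_id = h$hub_id, responder_id = resp, true_r = h$loading)
  })
  truth$planted_pairs <- planted
  list(expression = expression_matrix(X, "array"), truth = truth)
}

#' Simulate a replication cohort from the same planted structure
#'
#' Draws fresh samples under the structural spec of an existing ground truth,
#' then removes each non-hub feature independently with probability
#' `feature_dropout_rate`, emulating transcripts undetected on the
#' replication platform.
#'
#' @param spec The [simulation_spec()] used for the discovery cohort (its
#'   `replication` element supplies the cohort size and dropout rate).
#' @param truth Ground truth from [simulate_cohort()].
#' @return An `expr_matrix` with `replication$n_samples_rep` samples and a
#'   (random) subset of the discovery features.
#' @export
simulate_replication <- function(spec, truth) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(split_seed(spec$rng_seed, 2L))
  X <- draw_array_block(spec, spec$replication$n_samples_rep, truth)
  roles_arr <- truth$roles[truth$roles$platform == "array", ]
  is_hub <- roles_arr$role == "hub"
  drop <- stats::runif(nrow(X)) < spec$replication$feature_dropout_rate & !is_hub
  expression_matrix(X[!drop, , drop = FALSE], "array")
}

#' Simulate a binding-site annotation over the cohort features
#'
#' Labels each responder with probability `enriched_rate` and every other
#' array feature with probability `background_rate`, emulating a ChIP-derived
#' transcription-factor target gene set in which the hub's regulon is
#' enriched over a substantial genomic background rate.
#'
#' @param truth Ground truth from [simulate_cohort()].
#' @param enriched_rate Annotation probability for responders.
#' @param background_rate Annotation probability for all other array
#'   features.
#' @param rng_seed Integer seed.
#' @return Character vector of annotated feature IDs.
#' @export
simulate_annotation <- function(truth,
                                enriched_rate = truth$spec$enriched_annotation_rate,
                                background_rate = truth$spec$background_annotation_rate,
                                rng_seed = split_seed(truth$spec$rng_seed, 3L)) {
  assert_scalar_number(enriched_rate, "enriched_rate", 0, 1)
  assert_scalar_number(background_rate, "background_rate", 0, 1)
  roles <- truth$roles[truth$roles$platform == "array", ]
  set.seed(rng_seed)
  p <- ifelse(roles$role == "responder", enriched_rate, background_rate)
  roles$feature_id[stats::runif(nrow(roles)) < p]
}

#' Append a miRNA PCR layer to a simulated cohort
#'
#' Each simulated miRNA couples negatively (loading beta = `coupling`) to a
#' designated target transcript already present in the cohort, so the
#' miRNA-target population correlation is beta. Values are expressed on a
#' Ct-like scale (affine map of the latent signal into \[18, 36\], lower Ct =
#' more abundant) and a `ct_dropout_rate` fraction of cells fails to amplify
#' (missing), emulating PCR detection dropout. Inside the returned matrix the
#' PCR rows are stored as inverse-Ct, consistent with [load_expression()].
#'
#' @param spec The cohort's [simulation_spec()] (`pcr_block` element).
#' @param cohort Result of [simulate_cohort()].
#' @return List: `expression` (the cohort `expr_matrix` with miRNA rows
#'   appended), `truth` (roles extended with the miRNA features),
#'   `mirna_pairs` tibble of (mirna_id, target_id, true_r).
#' @export
simulate_mirna_layer <- function(spec, cohort) {
  stopifnot(inherits(spec, "simulation_spec"))
  pb <- spec$pcr_block
  if (pb$n_mirna < 1) return(c(cohort, list(mirna_pairs = tibble())))
  set.seed(split_seed(spec$rng_seed, 4L))
  em <- cohort$expression
  n <- ncol(em$values)
  roles <- cohort$truth$roles
  # targets: responders first (they carry planted structure), then background
  cand <- c(roles$feature_id[roles$role == "responder"],
            roles$feature_id[roles$role == "background"])
  targets <- cand[seq_len(pb$n_mirna)]
  beta <- pb$coupling
  mid <- sprintf("MIR%03d", seq_len(pb$n_mirna))
  ct <- matrix(NA_real_, nrow = pb$n_mirna, ncol = n,
               dimnames = list(mid, colnames(em$values)))
  for (i in seq_len(pb$n_mirna)) {
    x <- em$values[targets[i], ]
    core <- beta * (x - mean(x)) / stats::sd(x) +
      sqrt(1 - beta^2) * rnorm(n, sd = spec$noise_sd)
    ct_i <- 27 - 2 * core # lower Ct = more abundant
    ct_i <- pmin(36, pmax(18, ct_i))
    ct_i[stats::runif(n) < pb$ct_dropout_rate] <- NA_real_ # failed to amplify
    ct[i, ] <- ct_i
  }
  vals <- rbind(em$values, -ct) # inverse-Ct in memory
  platform <- c(unname(em$platform), rep("pcr", pb$n_mirna))
  mirna_roles <- tibble(feature_id = mid, role = "mirna",
                        hub_id = NA_character_, platform = "pcr")
  truth <- cohort$truth
  truth$roles <- dplyr::bind_rows(truth$roles, mirna_roles)
  list(expression = expression_matrix(vals, platform),
       truth = truth,
       mirna_pairs = tibble(mirna_id = mid, target_id = targets,
                            true_r = beta))
}

#' Feature annotation table for a simulated cohort
#'
#' Builds the annotation TSV contents matching a simulated ground truth:
#' sequential Entrez-like IDs and accessions, gene symbols equal to the
#' feature IDs, hub gene titles containing "transcription factor" (so the
#' TF-only output filter has something to find), and simple GO term strings.
#'
#' @param truth Ground truth (roles must cover every feature present).
#' @return Annotation tibble in the [load_annotation()] schema.
#' @export
simulate_feature_annotation <- function(truth) {
  roles <- truth$roles
  n <- nrow(roles)
  title <- dplyr::case_match(roles$role,
    "hub" ~ "synthetic transcription factor hub",
    "responder" ~ "synthetic hub-responsive transcript",
    "mirna" ~ "synthetic microRNA",
    .default = "synthetic background transcript")
  go <- dplyr::case_match(roles$role,
    "hub" ~ "GO:0006355 regulation of transcription|GO:0003700 DNA-binding transcription factor activity",
    "responder" ~ "GO:0007165 signal transduction",
    "mirna" ~ "GO:0035195 gene silencing by miRNA",
    .default = "GO:0008150 biological process")
  tibble(
    probe_set_id = roles$feature_id,
    entrez_id = as.character(seq_len(n) + 100000L),
    gene_symbol = roles$feature_id,
    accessions = sprintf("NM_%06d|XM_%06d", seq_len(n), seq_len(n) + 500000L),
    gene_title = title,
    go_terms = go
  )
}

#' Write all files of a simulated study to a directory
#'
#' Materialises the discovery expression TSV (with the miRNA PCR layer on
#' the Ct scale), replication expression TSV, annotation TSV, binding-site
#' gene-set file, miRNA-target pair list and a ground-truth JSON.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulated_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(spec)
  full <- simulate_mirna_layer(spec, cohort)
  rep_em <- simulate_replication(spec, cohort$truth)
  gene_set <- simulate_annotation(cohort$truth)
  ann <- simulate_feature_annotation(full$truth)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    replication = file.path(dir, "replication.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    gene_set = file.path(dir, "binding_sites.txt"),
    mirna_pairs = file.path(dir, "mirna_pairs.tsv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression(full$expression, paths$expression)
  write_expression(rep_em, paths$replication)
  readr::write_tsv(ann, paths$annotation, progress = FALSE)
  writeLines(c("# synthetic binding-site gene set", gene_set), paths$gene_set)
  readr::write_tsv(full$mirna_pairs[c("mirna_id", "target_id")],
                   paths$mirna_pairs, progress = FALSE)
  jsonlite::write_json(
    list(roles = full$truth$roles, planted_pairs = cohort$truth$planted_pairs,
         mirna_pairs = full$mirna_pairs, rng_seed = spec$rng_seed),
    paths$truth, dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Preset simulation specs
#'
#' `"mini"` (default everywhere in the test-suite): 105 samples x 2,000
#' features, one hub with 200 responders at loading 0.8. `"oslo-like"`:
#' 105 samples x 17,328 features (the full cohort scale; slow, for
#' benchmarking only).
#'
#' @param preset `"mini"` or `"oslo-like"`.
#' @param rng_seed Integer seed.
#' @return A [simulation_spec()].
#' @export
preset_spec <- function(preset = c("mini", "oslo-like"), rng_seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "mini") {
    simulation_spec(rng_seed = rng_seed)
  } else {
    simulation_spec(n_features = 17328, rng_seed = rng_seed)
  }
}
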