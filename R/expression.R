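#' Construct an expression matrix object
#'
#' Container for a cohort expression grid: features in rows, samples in
#' columns. Array-platform rows hold log2-normalised signal values and must be
#' complete; PCR-platform rows hold inverse-Ct values (negated cycle
#' thresholds, so that larger = more abundant, matching the orientation of the
#' array signals) and may contain missing cells where a transcript failed to
#' amplify.
#'
#' @param values Numeric matrix (features x samples) with unique rownames
#'   (feature IDs) and colnames (sample IDs); `NA` marks missing cells.
#' @param platform Character vector, one of `"array"` or `"pcr"` per feature
#'   (recycled if length 1).
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, platform = "array") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix", class = "bloodcorr_invalid_argument")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("`values` needs rownames (feature IDs) and colnames (sample IDs)",
          class = "bloodcorr_invalid_argument")
  }
  if (anyDuplicated(fid)) {
    abort(paste0("duplicate feature IDs: ",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")),
          class = "bloodcorr_duplicate_feature")
  }
  if (anyDuplicated(sid)) {
    abort("duplicate sample IDs", class = "bloodcorr_invalid_argument")
  }
  platform <- rep_len(platform, nrow(values))
  if (!all(platform %in% c("array", "pcr"))) {
    abort('`platform` entries must be "array" or "pcr"',
          class = "bloodcorr_invalid_argument")
  }
  if (any(is.infinite(values))) {
    abort("all observed values must be finite", class = "bloodcorr_invalid_argument")
  }
  array_na <- platform == "array" & apply(is.na(values), 1, any)
  if (any(array_na)) {
    abort(paste0("array-platform rows may not contain missing cells: ",
                 paste(head(fid[array_na], 5), collapse = ", ")),
          class = "bloodcorr_invalid_argument")
  }
  structure(list(values = values, platform = setNames(platform, fid)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  n_pcr <- sum(x$platform == "pcr")
  cat(sprintf("<expr_matrix> %d features x %d samples (%d array, %d pcr), %d missing cells\n",
              nrow(x$values), ncol(x$values), nrow(x$values) - n_pcr, n_pcr,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature IDs of an expression matrix
#' @param x An `expr_matrix`.
#' @return Character vector of feature IDs.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Tidy an expression matrix into long form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per (feature, sample) cell: `feature_id`,
#'   `sample_id`, `platform`, `value` (`NA` where missing).
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    platform = rep(unname(x$platform), times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

#' Load a cohort expression TSV
#'
#' Reads a tab-delimited expression table (header row of sample IDs, first
#' column `feature_id`, optional second column `platform` tagging each row
#' `array` or `pcr`). PCR rows are given on the cycle-threshold (Ct) scale and
#' are transformed to inverse-Ct (`-Ct`) on load; cells that are empty, `NA`,
#' or at/above `ct_sentinel` (the "no amplification" code many instruments
#' emit, default 40) become missing. By default PCR features that fail the
#' detection criterion (see [detect_features()]) are dropped, with the report
#' attached as attribute `"detection_report"`.
#'
#' @param path Path to the TSV file.
#' @param ct_sentinel Ct value at/above which a PCR cell is treated as
#'   not amplified (default 40). Applied on the Ct scale, before negation.
#' @param apply_detection Drop PCR features failing detection (default TRUE).
#' @param min_detected_fraction,ct_max Detection criterion, passed to
#'   [detect_features()].
#' @return An `expr_matrix`; attribute `"detection_report"` holds the
#'   per-feature detection tibble when `apply_detection` is TRUE.
#' @export
load_expression <- function(path, ct_sentinel = 40, apply_detection = TRUE,
                            min_detected_fraction = 0.5, ct_max = 35) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(readr::problems(raw)) > 0) {
    pr <- readr::problems(raw)
    abort(sprintf("malformed expression TSV at line %d: %s",
                  pr$row[1] + 1L, pr$expected[1]),
          class = "bloodcorr_parse_error")
  }
  if (names(raw)[1] != "feature_id") {
    abort('expression TSV must start with a "feature_id" column',
          class = "bloodcorr_parse_error")
  }
  fid <- raw$feature_id
  if (anyDuplicated(fid)) {
    dup <- unique(fid[duplicated(fid)])
    line <- which(fid == dup[1])[2] + 1L
    abort(sprintf("duplicate feature ID %s at line %d", dup[1], line),
          class = "bloodcorr_duplicate_feature")
  }
  has_platform <- identical(names(raw)[2], "platform")
  platform <- if (has_platform) raw$platform else rep("array", nrow(raw))
  value_cols <- names(raw)[-seq_len(1L + has_platform)]
  if (length(value_cols) == 0) {
    abort("expression TSV has no sample columns", class = "bloodcorr_parse_error")
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(value_cols),
                 dimnames = list(fid, value_cols))
  for (j in seq_along(value_cols)) {
    cell <- raw[[value_cols[j]]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- !missing & is.na(num)
    if (any(bad)) {
      abort(sprintf('non-numeric cell "%s" at line %d, column %s',
                    cell[which(bad)[1]], which(bad)[1] + 1L, value_cols[j]),
            class = "bloodcorr_parse_error")
    }
    vals[, j] <- ifelse(missing, NA_real_, num)
  }
  pcr <- platform == "pcr"
  if (any(pcr)) {
    block <- vals[pcr, , drop = FALSE]
    block[!is.na(block) & block >= ct_sentinel] <- NA_real_
    vals[pcr, ] <- -block # Ct -> inverse-Ct
  }
  em <- expression_matrix(vals, platform)
  if (apply_detection) {
    report <- detect_features(em, min_detected_fraction = min_detected_fraction,
                              ct_max = ct_max)
    dropped <- report$feature_id[!report$retained]
    if (length(dropped) > 0) {
      em <- expression_matrix(em$values[report$retained, , drop = FALSE],
                              em$platform[report$retained])
    }
    attr(em, "detection_report") <- report
  }
  em
}

#' Per-feature detection filtering
#'
#' Array features are always retained. A PCR feature is retained iff its Ct
#' value is below `ct_max` (equivalently inverse-Ct above `-ct_max`) in at
#' least `min_detected_fraction` of the samples. This is the "reached
#' detection level" criterion that decides whether a PCR transcript is
#' quantifiable in enough samples to correlate.
#'
#' @param em An `expr_matrix` (PCR rows on the inverse-Ct scale).
#' @param min_detected_fraction Required fraction of detected samples,
#'   in (0, 1\] (default 0.5).
#' @param ct_max Ct threshold for a single cell to count as detected
#'   (default 35).
#' @return A tibble with one row per feature: `feature_id`, `platform`,
#'   `n_detected`, `n_samples`, `detected_fraction`, `retained`.
#' @export
detect_features <- function(em, min_detected_fraction = 0.5, ct_max = 35) {
  stopifnot(inherits(em, "expr_matrix"))
  assert_scalar_number(min_detected_fraction, "min_detected_fraction",
                       lower = 1e-12, upper = 1)
  n_samples <- ncol(em$values)
  detected <- !is.na(em$values)
  is_pcr <- em$platform == "pcr"
  if (any(is_pcr)) {
    # inverse-Ct scale: detected means Ct < ct_max, i.e. value > -ct_max
    detected[is_pcr, ] <- detected[is_pcr, , drop = FALSE] &
      (em$values[is_pcr, , drop = FALSE] > -ct_max)
  }
  n_det <- rowSums(detected)
  frac <- n_det / n_samples
  tibble(
    feature_id = rownames(em$values),
    platform = unname(em$platform),
    n_detected = unname(as.integer(n_det)),
    n_samples = n_samples,
    detected_fraction = unname(frac),
    retained = unname(!is_pcr | frac >= min_detected_fraction)
  )
}

#' Write an expression matrix to TSV
#'
#' Inverse of [load_expression()]: PCR rows are written back on the Ct scale
#' (negated), missing cells as empty fields.
#'
#' @param em An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  vals <- em$values
  pcr <- em$platform == "pcr"
  vals[pcr, ] <- -vals[pcr, , drop = FALSE]
  df <- data.frame(feature_id = rownames(vals), platform = unname(em$platform),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}
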