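#' Load a feature annotation TSV
#'
#' Reads the probe-set annotation table used for identifier resolution and
#' output filtering. The file must have a header with a `probe_set_id`
#' column; `entrez_id`, `gene_symbol`, `accessions` (multiple accessions
#' separated by `,`, `;` or `|`), `gene_title` and `go_terms` (same
#' separators) are optional and may be empty for any row.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with one row per probe set, columns `probe_set_id`,
#'   `entrez_id`, `gene_symbol`, `accessions`, `gene_title`, `go_terms`
#'   (missing input columns filled with `NA`).
#' @export
load_annotation <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"probe_set_id" %in% names(tab)) {
    abort('annotation TSV must have a "probe_set_id" column',
          class = "bloodcorr_schema_error")
  }
  if (anyDuplicated(tab$probe_set_id)) {
    dup <- unique(tab$probe_set_id[duplicated(tab$probe_set_id)])
    abort(paste0("duplicate probe_set_id: ", paste(head(dup, 5), collapse = ", ")),
          class = "bloodcorr_schema_error")
  }
  for (col in c("entrez_id", "gene_symbol", "accessions", "gene_title", "go_terms")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab[c("probe_set_id", "entrez_id", "gene_symbol", "accessions",
        "gene_title", "go_terms")]
}

split_tokens <- function(x) {
  strsplit(ifelse(is.na(x), "", x), "[,;|] *")
}

#' Resolve a free-form identifier to probe-set IDs
#'
#' Accepts an Affymetrix probe-set ID, an Entrez Gene ID, an accession number
#' or a gene symbol, case-insensitively, and returns every probe set matching
#' at the first non-empty tier in the precedence order probe-set ID, then
#' Entrez, then accession, then symbol. Matching is exact after case-folding;
#' identifiers are never substring-matched. A symbol may map to multiple
#' probe sets, all of which are returned.
#'
#' @param annotation Annotation tibble from [load_annotation()].
#' @param query Non-empty identifier string.
#' @return Character vector of matching probe-set IDs (possibly empty).
#' @examples
#' ann <- tibble::tibble(probe_set_id = c("ps1", "ps2"),
#'                       entrez_id = c("1234", "5566"),
#'                       gene_symbol = c("NR3C1", "CREB1"),
#'                       accessions = c("NM_005715", ""),
#'                       gene_title = NA, go_terms = NA)
#' resolve_identifier(ann, "nr3c1")
#' @export
resolve_identifier <- function(annotation, query) {
  if (!is.character(query) || length(query) != 1L || is.na(query) ||
      !nzchar(trimws(query))) {
    abort("`query` must be a non-empty string", class = "bloodcorr_invalid_argument")
  }
  q <- tolower(trimws(query))
  fold <- function(x) tolower(trimws(x))
  hit <- fold(annotation$probe_set_id) == q
  if (any(hit)) return(annotation$probe_set_id[hit])
  hit <- !is.na(annotation$entrez_id) & fold(annotation$entrez_id) == q
  if (any(hit)) return(annotation$probe_set_id[hit])
  hit <- purrr::map_lgl(split_tokens(annotation$accessions),
                        function(a) q %in% fold(a))
  if (any(hit)) return(annotation$probe_set_id[hit])
  hit <- !is.na(annotation$gene_symbol) & fold(annotation$gene_symbol) == q
  annotation$probe_set_id[hit]
}

#' Query specification for neighbor searches
#'
#' Bundles the output restrictions of a correlation search: correlation sign,
#' a GO keyword (case-insensitive substring of any GO term of the partner),
#' and the transcription-factor shortcut (partner's gene title contains
#' "transcription").
#'
#' @param sign Keep only `"positive"` (r > 0), `"negative"` (r < 0) or
#'   `"both"` (default). A coefficient of exactly 0 carries no sign and is
#'   excluded by both one-sided filters.
#' @param go_keyword Optional substring to require among the partner's GO
#'   terms.
#' @param tf_only If TRUE keep only partners whose gene title contains
#'   "transcription".
#' @param max_results Cap on returned rows (default unlimited).
#' @param family Multiple-testing family for Bonferroni correction,
#'   `"global"` or `"per_seed"`.
#' @return A `query_spec` object.
#' @export
query_spec <- function(sign = c("both", "positive", "negative"),
                       go_keyword = NULL, tf_only = FALSE,
                       max_results = Inf, family = c("global", "per_seed")) {
  sign <- match.arg(sign)
  family <- match.arg(family)
  if (!is.null(go_keyword)) stopifnot(is.character(go_keyword), length(go_keyword) == 1)
  stopifnot(isTRUE(tf_only) || isFALSE(tf_only))
  assert_scalar_number(max_results, "max_results", lower = 0)
  structure(list(sign = sign, go_keyword = go_keyword, tf_only = tf_only,
                 max_results = max_results, family = family),
            class = "query_spec")
}

#' Filter correlation records by annotation and sign
#'
#' Applies the output restrictions of a [query_spec()] to a table of
#' correlation records, keeping input order. Annotation-based filters
#' (GO keyword, TF-only) look up each record's `partner` in the annotation
#' table; records whose partner lacks the queried annotation fail the filter.
#'
#' @param records Tibble of correlation records with at least `partner` and
#'   `r` columns (as returned by [top_neighbors()]).
#' @param annotation Annotation tibble; required for `go_keyword` / `tf_only`.
#' @param spec A [query_spec()].
#' @return The filtered records, order preserved.
#' @export
apply_filters <- function(records, annotation, spec) {
  stopifnot(inherits(spec, "query_spec"))
  if (nrow(records) == 0) return(records)
  keep <- rep(TRUE, nrow(records))
  if (spec$sign == "positive") keep <- keep & !is.na(records$r) & records$r > 0
  if (spec$sign == "negative") keep <- keep & !is.na(records$r) & records$r < 0
  needs_ann <- !is.null(spec$go_keyword) || isTRUE(spec$tf_only)
  if (needs_ann) {
    if (is.null(annotation)) {
      abort("annotation table required for GO / TF filters",
            class = "bloodcorr_invalid_argument")
    }
    ai <- match(records$partner, annotation$probe_set_id)
    if (!is.null(spec$go_keyword)) {
      kw <- tolower(spec$go_keyword)
      terms <- split_tokens(annotation$go_terms[ai])
      keep <- keep & purrr::map_lgl(terms, function(tt) {
        any(grepl(kw, tolower(tt), fixed = TRUE) & nzchar(tt))
      })
    }
    if (isTRUE(spec$tf_only)) {
      title <- annotation$gene_title[ai]
      keep <- keep & !is.na(title) & grepl("transcription", tolower(title),
                                           fixed = TRUE)
    }
  }
  records[keep, , drop = FALSE]
}
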