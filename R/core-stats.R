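#' Pearson correlation over pairwise-complete observations
#'
#' Computes the Pearson product-moment correlation between two expression
#' profiles, using only sample positions where both values are observed.
#' When fewer than `min_n` pairwise-complete observations remain, the pair is
#' flagged undetected and no coefficient or p-value is reported; this is how
#' PCR features with heavy detection dropout are kept out of the matrix
#' without discarding the record entirely.
#'
#' @param x,y Numeric vectors of equal length; `NA` marks a missing
#'   (undetected) measurement.
#' @param min_n Minimum number of pairwise-complete observations required to
#'   report a coefficient (default 20; must be at least 3 so the t-based
#'   p-value has positive degrees of freedom).
#' @return A one-row tibble with columns `r`, `n_obs`, `p_raw` and `detected`.
#'   For an undetected pair `r` and `p_raw` are `NA` and `detected` is FALSE.
#' @details A feature with zero variance over the complete positions has no
#'   defined correlation with anything; that is signalled as an error of class
#'   `bloodcorr_degenerate_feature`, deliberately distinct from the
#'   undetected case.
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8), min_n = 3)
#' pearson_r(c(1, 2, 3, NA), c(3, 2, NA, 1), min_n = 3) # undetected: n_obs = 2
#' @export
pearson_r <- function(x, y, min_n = 20) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length",
          class = "bloodcorr_invalid_argument")
  }
  assert_scalar_number(min_n, "min_n", lower = 3)
  ok <- !is.na(x) & !is.na(y)
  n_obs <- sum(ok)
  if (n_obs < min_n) {
    return(tibble(r = NA_real_, n_obs = n_obs, p_raw = NA_real_,
                  detected = FALSE))
  }
  xs <- x[ok]
  ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    abort("zero variance over the pairwise-complete observations",
          class = "bloodcorr_degenerate_feature")
  }
  r <- stats::cor(xs, ys)
  tibble(r = r, n_obs = n_obs, p_raw = correlation_pvalue(r, n_obs),
         detected = TRUE)
}

#' Two-sided p-value for a Pearson correlation coefficient
#'
#' Uses the classical transform t = r * sqrt((n - 2) / (1 - r^2)), referred to
#' Student's t distribution with n - 2 degrees of freedom. Coefficients within
#' 1e-15 of +/-1 are treated as exactly +/-1 (p = 0) to avoid division blowup
#' in floating point. Vectorised over `r` and `n_obs`.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param n_obs Number(s) of paired observations; must be >= 3.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @examples
#' correlation_pvalue(0.5, 20)
#' correlation_pvalue(0, 10) # exactly 1
#' @export
correlation_pvalue <- function(r, n_obs) {
  if (any(is.na(n_obs)) || any(n_obs < 3)) {
    abort("p-value undefined for n_obs < 3 (needs n_obs - 2 >= 1 df)",
          class = "bloodcorr_undefined_p")
  }
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    abort("|r| > 1", class = "bloodcorr_invalid_argument")
  }
  r <- pmin(1, pmax(-1, r))
  p <- rep(NA_real_, length(r))
  perfect <- !is.na(r) & abs(r) >= 1 - 1e-15
  p[perfect] <- 0
  idx <- !is.na(r) & !perfect
  if (any(idx)) {
    nn <- rep_len(n_obs, length(r))[idx]
    tstat <- r[idx] * sqrt((nn - 2) / (1 - r[idx]^2))
    p[idx] <- 2 * stats::pt(abs(tstat), df = nn - 2, lower.tail = FALSE)
  }
  p
}

#' Bonferroni correction
#'
#' Family-wise error control by multiplying each raw p-value by the family
#' size and clamping at 1.
#'
#' @param p_raw Raw p-value(s) in \[0, 1\].
#' @param m Family size (number of tests), >= 1.
#' @return Adjusted p-value(s) `pmin(1, p_raw * m)`.
#' @examples
#' bonferroni(2e-4, 100)
#' bonferroni(0.5, 10) # clamps at 1
#' @export
bonferroni <- function(p_raw, m) {
  assert_scalar_number(m, "m", lower = 1)
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "bloodcorr_invalid_argument")
  }
  pmin(1, p_raw * m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values: after sorting p ascending,
#' q_(i) = min over j >= i of p_(j) * m / j, mapped back to input order.
#' Rejecting q <= alpha reproduces the BH step-up rejection set exactly.
#' `NA` p-values are excluded from the family and returned as `NA`; `m`
#' defaults to the number of non-missing p-values but may be set larger when
#' the nominal family includes tests that produced no p-value (e.g.
#' undetected pairs).
#'
#' @param p_values Vector of raw p-values in \[0, 1\] (`NA` allowed).
#' @param m Family size; defaults to the number of non-`NA` p-values, must be
#'   at least that.
#' @return Vector of BH-adjusted values, same length and order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
#' bh_fdr(c(0.005, 0.5))
#' @export
bh_fdr <- function(p_values, m = NULL) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "bloodcorr_invalid_argument")
  }
  n_eff <- sum(!is.na(p_values))
  m <- m %||% n_eff
  if (m < n_eff) {
    abort("family size `m` smaller than the number of p-values",
          class = "bloodcorr_invalid_argument")
  }
  out <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH", n = m)
  out
}
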