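---
title: "Methods: the all-pairs blood transcript correlation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the all-pairs blood transcript correlation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodcorr)
```

## The model

The package treats a cohort expression matrix — features (microarray probe
sets plus PCR-quantified small RNAs) in rows, donors in columns — as a
collection of paired observations and asks, for every unordered pair of
features, how strongly their signals co-vary across donors. The statistic is
the Pearson product-moment correlation $r$, computed on log2-normalised
array signals and on *inverse-Ct* values for PCR features. Significance uses
the classical transform

$$ t = r\,\sqrt{\frac{n-2}{1-r^2}} \sim t_{n-2} $$

two-sided. The source data never state which test generated their p-values;
the $t$ transform is the standard choice for product-moment correlation and
is adopted here as the package's default and only method (rank-based and
permutation alternatives are out of scope).

With $F$ retained features there are $F(F-1)/2$ tests — at the full cohort
scale of 17,328 transcripts, 150,121,128 of them — so every record carries
two corrections: Bonferroni ($\min(1, p\,m)$) and the Benjamini–Hochberg
step-up FDR adjustment. Both are *derived at query time* from the stored
$(r, n_{\mathrm{obs}})$, which lets the family $m$ be chosen per query:

* **global** family, $m = F(F-1)/2$: matches the framing of one giant
  correlation matrix. Default for Bonferroni.
* **per-seed** family, $m = F-1$: the tests actually performed by one
  neighbor scan. Default for BH, since FDR is reported on search results.

For a single pair record the per-seed BH family is anchored at the
lexicographically smaller member of the pair, so that
`lookup_pair(a, b)` and `lookup_pair(b, a)` are identical — the family seed
would otherwise be ambiguous. A global BH q is available but costs a pass
over every stored pair.

## Missing data and detection

Array rows must be complete. PCR rows arrive on the cycle-threshold scale,
where *lower* Ct means more template; they are reoriented on load as
inverse-Ct $= -\mathrm{Ct}$, a monotone reversal that preserves the spacing
of the cycle scale ($1/\mathrm{Ct}$ would also reverse orientation but
distorts spacing; the transform the original study used is not recorded).
Three per-feature/per-pair rules then govern what enters the matrix:

* **Detection** (`detect_features()`): a PCR feature is retained iff
  Ct < `ct_max` (default 35 cycles) in at least `min_detected_fraction`
  (default 50%) of samples. The criterion behind the original "reached
  detection level" phrase is unrecorded; these defaults are ordinary
  qPCR practice and both knobs are exposed.
* **Pairwise completeness**: a pair's $r$ uses only samples where both
  features are observed; if fewer than `min_n` (default 20) remain, the
  pair is kept but flagged *undetected* — distinct from absent.
* **Degeneracy**: a zero-variance feature has no defined correlation with
  anything and is excluded at build time with a warning, so the store never
  holds NaN records.

## The store

`build_store()` standardises every complete row once and accumulates block
outer products (`tcrossprod` over feature blocks), falling back to
pairwise-complete computation only for rows with missingness; a naive
per-pair loop serves as the test oracle for both paths. The payload is 6
bytes per pair — $r$ as little-endian float32, $n_{\mathrm{obs}}$ as uint16 —
behind a JSON metadata header in a single file. Storing only
$(r, n_{\mathrm{obs}})$ halves the footprint of a 150M-pair matrix
(~900 MB) and means no correction family is baked in at build time.
Float32 quantisation perturbs $r$ by at most ~6e-8, negligible against the
~1e-2 sampling scale of $r$ at $n = 105$; the in-memory store is quantised
at build so memory, disk and any re-read agree bit for bit, which is also
what makes rebuilds byte-identical and testable as such.

Pairs live at arithmetically computed condensed-triangle offsets, so
symmetric lookup and a seed's full neighbor scan need no stored index.
`top_neighbors()` ranks by raw p ascending with deterministic tie-breaking
(larger $|r|$, then lexicographic partner ID), computes BH q over the seed's
full $F-1$ family *before* any filter or truncation, and only then applies
annotation filters (GO keyword substring, the "transcription in the gene
title" TF shortcut, correlation sign — $r = 0$ exactly satisfies neither
sign) and the cut to $k$.

Identifier resolution accepts probe-set IDs, Entrez IDs, accessions and
gene symbols, case-insensitively, with exact matching after case folding.
The precedence order probe set → Entrez → accession → symbol is this
package's choice (the original interface lists the accepted types without
ordering them); a fixed precedence prevents a token that is simultaneously
someone's probe ID and someone else's Entrez ID from silently merging two
genes, and an identifier hitting several probe sets at one tier returns all
of them.

## Validation procedures

**Binding-site enrichment.** For a seed transcription factor, take its top
$k$ (default 200) correlates, deduplicate to gene level, and measure the
fraction carrying the TF's binding-site annotation. The baseline is
resampling-based, not hypergeometric, mirroring how the original check was
done: $R$ (default 1,000, unrecorded in the source) draws of $k$ genes
without replacement from the detected-gene universe excluding the seed,
summarised as mean ± SD, with the add-one empirical p-value
$(1 + \#\{\text{draws} \ge \text{observed}\})/(R+1)$, which can never be 0.
Note the universe deliberately includes the seed's own correlates (random
genes "from the same cohort"), so when a regulon is both large and heavily
annotated, the baseline mean sits slightly above the background annotation
rate; the resampling SD, not the SD of the mean, is the scale on which that
gap is judged in the package's tests.

**Replication accounting.** Carried-forward pairs are recomputed in a
second cohort and classified `significant` / `nonsignificant` /
`undetected` (either member absent, or below `min_n` overlap), with
Bonferroni over the carried-forward family (default: the number of tested
pairs; the original family size is unrecorded, and the whole-matrix
alternative is available via `family_size`). The three counts summing to
the input count is enforced as a hard assertion, not just tested.

**miRNA-target recall.** For curated miRNA–mRNA interaction pairs, the
report counts pairs reaching detection in the store and the fraction of
those with nominal (uncorrected) $p < \alpha$; the anti-correlated subset
($r < 0$, the direction miRNA-mediated decay predicts) is reported
separately rather than imposed, since the source analysis did not restrict
sign.

## The synthetic cohort generator

Real cohort data is large and access-controlled; the generator produces
cohorts with the statistical structure the engine assumes, with known
ground truth:

* Each **hub** $h$ (a TF stand-in) has a latent factor
  $z_h \sim N(0,1)$ per sample and reports it directly; each of its
  $n_{\mathrm{responders}}$ **responders** is
  $\lambda z_h + \sqrt{1-\lambda^2}\,\varepsilon$. Every array feature has
  population variance 1 and the planted hub–responder correlation is
  *exactly* $\lambda$ (co-responders correlate at $\lambda^2$), which makes
  recovery, bias and power checkable in closed form.
* **Background** features are independent noise.
* The **miRNA layer** couples each simulated miRNA to a designated target
  at loading $\beta \le 0$, maps the signal affinely onto a Ct-like scale
  in [18, 36], and knocks out cells at `ct_dropout_rate` to emulate
  amplification failure.
* The **replication cohort** redraws samples from the same structure and
  removes non-hub features independently at `feature_dropout_rate`,
  emulating platform dropout.
* The **annotation** labels responders at `enriched_rate` and everything
  else at `background_rate`.

Defaults are the study design the engine targets: 105 discovery samples,
1,204 replication samples with 7% feature dropout, loading 0.8 for one
200-gene regulon, annotation rates 0.91 over 0.483, coupling −0.6 for ten
miRNAs. The default `"mini"` preset uses 2,000 features rather than 17,328
so an end-to-end build is ~2M pairs; the test-suite and the acceptance
script run everything at that scale (the full scale changes only the pair
count, which is verified arithmetically). All randomness fans out from one
spec-level seed through fixed stream offsets, so the discovery cohort,
replication cohort, annotation and miRNA layer are independently
reproducible.

What the generator does *not* emulate — probe-level microarray noise, batch
structure, clinical covariates, heavy-tailed expression distributions,
correlated background modules — bounds what green tests mean: they show the
engine computes, stores, ranks, corrects and validates correctly under the
assumed factor model, not that any particular biological association is
real.

## Numerical choices

* $|r| \ge 1 - 10^{-15}$ is clamped before the $t$ transform; $p = 0$.
* BH over a family containing undetected neighbors uses the nominal family
  size $F - 1$ with the undetected tests contributing no p-value — the
  conservative direction.
* Ties in the neighbor ranking are broken by larger $|r|$, then partner ID,
  so output is a deterministic function of (store, arguments).
* The empirical enrichment p uses the add-one correction, making it valid
  (super-uniform under exchangeability) at finite $R$.

## Limitations

Pearson correlation on a 105-sample cohort detects linear, monotone
co-variation; the engine inherits every caveat of that statistic
(sensitivity to outliers, blindness to non-linear coupling). The BH
procedure's FDR guarantee assumes independent or positively dependent
tests — reasonable for co-expression screens, argued informally, not
verified per dataset. The store loads its payload fully into memory on
read; the full 17,328-feature matrix fits in a few GB but streaming access
is not implemented. Incremental store updates and ontology-aware GO
filtering are out of scope.
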