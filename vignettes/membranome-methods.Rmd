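---
title: "Methods: comparative membranome expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative membranome expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery of the package, the
assumptions behind it, and the design choices made where the methodology
was genuinely open. The package targets meta-analyses of bulk expression
compendia that combine tumor-derived cell lines, primary tumors and
normal tissues from multiple studies on one platform, and asks how the
expression of plasma-membrane protein genes (the *membranome*) behaves
across those three settings.

## Catalog model

Membranome membership is decided per gene from four evidence channels:
compartment annotation terms, a predicted transmembrane segment, a
predicted signal peptide, and manual override lists. The decision rule is

> member ⇔ manually included, or a plasma-membrane accept-term is present,
> or a transmembrane domain is predicted and no intracellular reject-term
> is present — unless manually excluded.

A signal peptide alone is deliberately *not* sufficient: secreted
proteins carry one too. Manual inclusion exists for proteins the
automatic channels miss structurally — GPI-anchored proteins are the
canonical case, membrane-associated without any transmembrane helix.
Accept/reject term lists ship as editable configuration rather than
hard-coded ontology identifiers because ontology releases drift; the
rule logic, not a term snapshot, is the contract. Reported percentages
round to the nearest integer with ties away from zero.

The per-category platform-representation test is a two-sided Fisher exact
test of the 2×2 table (category / not-category) × (on-array / off-array)
restricted to catalog members. Note the direction of interest is
*preserved composition*, i.e. large p-values; a category can also be
significantly under-represented (typically poorly annotated genes, which
array designs historically disfavor). Both readings are possible from the
same table, so the per-category p-values are reported without a single
verdict.

## Preprocessing chain

The chain is fixed in this order, with a `scale_state` guard that refuses
to run stages on the wrong scale:

1. **Replicate averaging** (arithmetic mean per gene within a technical
   replicate group; a group spanning tissues or classes is an error).
2. **Trimmed-mean scaling**: each array is multiplied by
   `target / trimmed_mean(column)` with target 500 (the array-processing
   convention) and a trim fraction of 0.02 by default — the trimmed mean
   discards the lowest and highest 2% of intensities, making the scale
   factor robust to saturated probes. The trim fraction is configurable
   since the upstream summarization does not pin it.
3. **Quantile normalization** forces all arrays onto the mean-order-
   statistic distribution; tied values receive the mean of their tied
   positions' reference values (mid-rank). On continuous (tie-free) data
   the operation is exactly idempotent; with ties, mid-rank averaging
   perturbs the shared multiset slightly, which is the standard trade-off
   of that tie rule. Whether normalization should span all arrays jointly
   or per comparison group is not determined by the method; the package
   normalizes whatever dataset it is handed, and the default workflow
   loads all arrays jointly.
4. **log2 transform** with a floor (default 1.0 on the linear scale) to
   avoid minus infinity at zero intensities.

## Nearest shrunken centroid classification

For gene *i* and class *k*, the standardized centroid offset is
`d_ik = (x̄_ik − x̄_i)/(m_k (s_i + s0))` with `m_k = sqrt(1/n_k − 1/n)`,
pooled within-class standard deviation `s_i`, and fudge factor `s0` set
to the median of the `s_i`. Soft-thresholding by Δ zeroes small offsets;
genes with any surviving offset are the classifier. Prediction minimizes
the squared standardized distance to the shrunken centroid minus twice
the log prior; priors default to class proportions, and score ties break
to the lexicographically smallest class label so results are
reproducible.

**Misclassification curves.** The published analysis compares equally
sized random gene lists from the membranome and from its complement,
re-running the classification many times per list size. The list-size
protocol was left ambiguous by the original description (list size and Δ
were conflated). The package's default protocol draws random lists of
exactly N genes and fits with Δ = 0, which makes "equally sized, randomly
chosen" literal and keeps the membranome/non-membranome comparison
exchangeable under the null; choosing Δ per replicate to hit a target
active-gene count remains possible through the fitting interface.
Misclassification is estimated by stratified 5-fold cross-validation
(the published procedure is unspecified; resubstitution error is also
computable but CV is reported), with folds redrawn per replicate from the
replicate's seed stream. The same per-replicate fold seed serves both
gene pools, so replicate rates pair naturally for the one-sided
comparison. Classes need at least 3 samples; for very small classes the
fold count adjusts (with a warning) so that every training split keeps at
least 2 samples per class.

**Exponential fits.** `rate = a·exp(−b·size) + c` is fitted by bounded
Levenberg–Marquardt least squares (b ≥ 0, c ∈ [0, 1]), initialized at
a = max − min rate, c = min rate, and b from a log-linear regression of
(rate − c) on size. Non-convergence is flagged and the best iterate
returned rather than erroring, since a flat curve (no size effect) is a
legitimate outcome.

## Tumor/cell-line similarity

Pearson correlation between every tumor sample and every cell line over
the membranome genes present on the platform (no variance filtering),
grouped by (tumor tissue, cell-line tissue). Zero-variance profiles give
undefined correlations, which are excluded with a warning and counted.
Boxplot-style summaries use type-7 (linear interpolation) quartiles —
stated explicitly because quartile conventions change the summaries.
Cognate-vs-non-cognate comparisons use Student's equal-variance t-tests
(the published choice); Welch is only a flagged fallback for degenerate
variances. The Bonferroni family is *all* cognate-vs-non-cognate tests
across all tumor tissues (8 × 7 = 56 in the full design) — the
conservative reading, since the original analysis does not state the
family.

## Permutation differential expression

The moderated statistic is `d(i) = (x̄₂ − x̄₁)/(s(i) + s0)` with the
pooled standard error
`s(i) = sqrt[(1/n₁ + 1/n₂)/(n₁ + n₂ − 2) · (Σ₁(x − x̄₁)² + Σ₂(x − x̄₂)²)]`.
The fudge factor `s0` is the percentile of the `s(i)` minimizing the
coefficient of variation of `d` across ten scale-quantile windows
(variation measured by the within-window MAD); the choice is
deterministic, and a degenerate all-equal scale vector is flagged.

Class labels are permuted — exhaustively when the number of distinct
assignments does not exceed the permutation budget B (default 300), which
makes the analysis seed-free on small groups — to obtain expected order
statistics and threshold tables. For each threshold Δ on the deviation
between observed and expected order statistics, cut points are found by
walking outward from the middle of the quantile-quantile display, and

FDR(Δ) = π̂0 · mean over permutations of #{permuted d beyond cuts} / n_called.

π̂0 is the count of observed d inside the interquartile range of the
pooled permuted d divided by n/2, capped at 1. Two numerical choices
matter here:

* **Mean, not median, of the exceedance counts.** The count distribution
  is right-skewed and integer-valued; at thresholds calling only one or
  two genes the *median* count collapses to zero whenever more than half
  the permutations show no exceedance, producing an estimated FDR of
  exactly 0 for what is actually a noise call. The mean never collapses,
  is the more conservative of the two, and restores the expected behavior
  that under pure noise the first calling threshold carries an estimated
  FDR near 1. The median remains available (`fdr_center = "median"`).
* **Threshold grid.** Candidate Δ values are the union of a quantile grid
  of the observed deviations (resolution where most genes live) and a
  uniform grid up to the maximum deviation (resolution in the sparse
  upper range where true effects live); a quantile grid alone steps over
  the interesting region.

Gene selection takes the smallest Δ with estimated FDR below the target
(0.01 throughout, the conservative published choice); if none achieves
it the lists are empty and flagged. Probe-level results collapse to gene
level by "called if any probe is called, direction by probe majority,
exact ties excluded". Balanced permutations are not enforced — the group
sizes in this design are small and unbalanced.

## MTDG consistency and overlap

Per tissue with all three sample classes, the tumor-vs-normal and
cell-line-vs-normal comparisons run at the same FDR target over the same
analyzed universe (membranome genes on the platform). Consistency
percentages use tumor-side denominators — `pct_up = 100·|t_up ∩ cl_up| /
|t_up|` — so they read as "of the deregulations seen in tumors, how many
do the cell lines retain". The combined percentage is exactly the
count-weighted mean of the directional ones.

The cross-tissue overlap matrix required choosing the 2×2 construction,
which the source analysis leaves unstated: the package treats the cell
line's deregulated set and the tumor's deregulated set as the margins and
counts only direction-consistent genes (up-with-up plus down-with-down)
in the intersection; a direction-blind switch is provided. P-values are
one-sided hypergeometric tails computed in log space, so −log10 p is
finite and exact even below the double-precision underflow point
(p < 1e−300). Entries print at one decimal.

## Gene-set enrichment

One-sided Fisher-exact (hypergeometric) enrichment over a universe that
defaults to the analyzed pool — membranome genes on the platform — rather
than the genome: the tested lists are drawn from that pool, so
conditioning on it is the standard choice (and configurable). P-values
are reported uncorrected by design: gene sets overlap heavily, violating
the independence assumptions of Bonferroni/Holm/FDR corrections, and the
reporting threshold (default p < 0.05) is a display filter, not an
inference claim.

## The synthetic compendium

`generate_dataset()` emulates the structure the analysis assumes, on the
log2 scale:

value = baseline + tissue signature + deregulation (tumors; retained
subset in cell lines) + TIL admixture (tumors only) + study batch offset
+ Gaussian noise.

Defaults, chosen once as the study conditions: eight tissues (brain,
breast, colon, kidney, leukemia, lung, melanoma, ovary); cell-line counts
6–9 per tissue matching the real compendium, with tumor (10–20) and
normal (7–20) group sizes scaled down from it; 2,500 genes of which 17%
are membranome; per-tissue signatures of 30 genes at +2 log2 units with
80% drawn from the membranome (`rho`); 40 up- and 40 down-regulated genes
planted per tissue within the membranome at ±1.5 log2 units — tumor-side
lists of ~80 genes, the low end of the published per-tissue MTDG list
sizes, large enough that binomial retention noise stays within a few
percentage points; retention probabilities `r_up = 0.5 < r_down = 0.8`
(the asymmetry under study: up-regulations are mostly lost in vitro,
down-regulations mostly kept); a 30-gene tumor-only immune-infiltrate
block (+1) absent from the clonal cell lines; per-study per-gene batch
offsets with SD 0.1; residual noise SD 0.4. Normal samples are generated
for all eight tissues even though the real compendium lacks them for
three; analyses requiring normals simply skip tissues without them.

Two generator choices deserve comment. Batch offsets are additive per
study and gene, and studies are confounded with sample class in the
emulated design (all cell lines share one study; each tissue's tumors and
normals are separate studies) — exactly as in real compendia assembled
from per-study submissions. Such offsets are a genuine non-null signal
for the tumor-vs-normal contrast: no label-permutation test can
distinguish them from biology. The default SD of 0.1 log2 units reflects
residual between-study variation *after* trimmed-mean scaling and
quantile normalization; raising it degrades the differential-expression
stage honestly (more confounded calls), which is itself informative, but
then the truth table no longer describes the truth of the tested
contrast. Correspondingly, "global null" simulations set both the
planted effects and the batch SD to zero. Second, noise is Gaussian on
the log2 scale — standard for normalized array intensities — so the
generator does not emulate heavy-tailed outliers, probe-level effects, or
intensity-dependent variance; passing tests demonstrate correctness of
the pipeline's logic under its own model, not robustness to those
real-data features.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at the
default compendium size (2,500 genes × 258 samples), 100 permutations per
differential-expression comparison, 100 resampling replicates per
classifier size, and 20 null-simulation seeds — sizes chosen so the whole
suite completes in well under a minute per stage on a single CPU while
keeping Monte Carlo error far inside the asserted tolerances. Every
stochastic stage takes an explicit integer seed and restores the caller's
RNG state; synthetic generation is bit-identical given its seed, and
permutation analyses are seed-independent whenever permutations are
exhaustive.

## Known limitations

* The catalog is only as good as its annotation inputs; the package
  ships rule logic, not a gene list.
* The permutation FDR inherits SAM's granularity at very small call
  counts; the mean-count estimator mitigates but cannot remove it.
* Study-batch confounding with sample class is diagnosable but not
  correctable here (no batch-correction stage is included, since the
  emulated published workflow had none beyond quantile normalization).
* Enrichment is strictly 2×2 overlap-based; rank-based (GSEA-style)
  enrichment is out of scope.
* Probe-to-gene collapsing assumes the supplied mapping; no sequence
  re-annotation is attempted.
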