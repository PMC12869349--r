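---
title: "Methods: compositional ecotype inference, signature scoring and survival stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional ecotype inference, signature scoring and survival stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tmeco)
```

This vignette is the package's account of its statistical methods: the
models and conventions each stage implements, the tunable parameters and
their defaults, what the synthetic-data generator does and does not
emulate, and the design choices made where the underlying workflow left the
design open. It states no empirical result that the test suite does not
itself compute.

## 1. Cell-level quality control

A cell is removed iff at least one rule triggers:

* fewer than `min_genes` (default 200) detected genes;
* any of UMIs, detected genes, or detected housekeeping genes below the
  **per-sample robust lower bound**
  `median − mad_multiplier × mad_scale × MAD`, with `mad_multiplier = 3`
  and `mad_scale = 1.4826` (the consistency constant that makes the MAD
  estimate a normal standard deviation; set `mad_scale = 1` for the raw
  MAD). Thresholds are computed per sample on raw metric values, on **all**
  cells of the sample before any removal;
* mitochondrial transcript fraction above `max_mito` (default 0.20);
* `is_doublet == TRUE`, when such a column is supplied. No doublet caller
  is implemented; upstream calls are only honoured.

Two consequences are deliberate and tested. First, the filter is
order-invariant and monotone in `max_mito`. Second, it is **not
idempotent**: thresholds are computed once, pre-removal, so re-applying QC
to an already filtered table recomputes the per-sample bands on the
survivors and may remove further cells. Run it once per raw table.

## 2. Composition and scaling

`build_composition()` tallies post-QC cells into a samples × subtypes
fraction matrix. Two denominator conventions are exposed because they
answer different questions: `all_cells` (fractions of the whole sample —
the ecotype substrate) and `parent_lineage` (fractions within the
subtype's parent lineage — the convention for subset-level dot plots,
where each lineage block of a row sums to 1).

`scale_composition()` standardises each subtype column across samples
(subtract the column mean, divide by the sample standard deviation,
`n − 1` denominator, matching R's `scale()`), mapping constant columns to
zeros. Standardisation is what makes rare subsets commensurate with
abundant lineages in the distance computation; the underlying workflow
says only that the proportion matrix is "scaled across cell types", and
z-standardisation is the assumption made here (it is what the pheatmap
convention implies).

## 3. Ecotype inference

`infer_ecotypes()` clusters samples by Euclidean distance between scaled
composition rows under Ward's minimum-variance criterion in the `ward.D2`
convention — unsquared Euclidean input, each merge minimising the increase
in total within-cluster sum of squares. The implementation delegates to
`stats::hclust(method = "ward.D2")`, the exact routine the pheatmap-based
workflow calls; the test suite checks it against an independent brute-force
agglomerator that recomputes within-cluster sums of squares for every
candidate pair at every merge (200 random instances, n ≤ 30), and merge
heights are checked to be monotone.

Choices made where the workflow is silent:

* **k selection.** The number of ecotypes is fixed at `k = 5` by default —
  the atlas this reproduces chose five by inspection — rather than
  automated. `silhouette_scan = TRUE` reports mean silhouette widths for
  k ∈ 2..10 but never changes `k`: reproducibility over automation.
* **Labelling.** Ecotype labels `E1..Ek` are assigned by decreasing group
  size. Naming by biology (T-cell-dominant, stromal, balanced, desert,
  myeloid-enriched) is a post-hoc annotation, implemented in
  `annotate_ecotypes()` as the argmax of mean lineage fraction per
  ecotype; the clustering itself never sees lineage labels.
* **Ties.** Tie-breaking among equal-cost merges follows `hclust`;
  dendrograms from other toolchains may differ on tied inputs. All oracle
  comparisons use continuous random data, where ties have probability
  zero.

`ecotype_group_distribution()` cross-tabulates assignments against stage,
cancer type, or their interaction, reporting counts, each ecotype's group
composition (rows summing to 100%), and each group's ecotype mix.
`export_dendrogram()` writes the tree as Newick (via `ape`), with merge
heights as ultrametric branch lengths.

## 4. Enrichment statistics

`pearson_residuals()` computes `R = (obs − exp)/√exp` with
`exp[i, j] = rowsum_i × colsum_j / N`. Positive residuals indicate
enrichment, negative depletion, and `ΣR²` equals the Pearson chi-square
statistic (an identity the tests verify against `chisq.test` on a thousand
random tables). Residuals are descriptive here; significance calls on the
companion dot plots come from `proportion_group_test()` — a two-sided
Wilcoxon rank-sum on per-sample fractions (exact when both groups have
≤ 25 observations and no ties, normal approximation with tie and
continuity correction otherwise; Kruskal–Wallis for ≥ 3 groups). No
multiple-testing correction is applied across subsets by default, matching
the reproduced figures; BH adjustment is available downstream.

`de_markers()` performs one-vs-rest two-sided rank-sum tests per gene
(vectorised normal approximation with tie correction), BH adjustment
within each contrast, and log2 fold changes on de-logged means with
pseudocount 1: `log2((mean(expm1(in)) + 1)/(mean(expm1(out)) + 1))`. A
gene is kept iff `log2FC > 0.4` **and** adjusted `p < 0.05`; clusters with
fewer than 3 cells are skipped with a warning. The rank-sum choice mirrors
the default of the upstream single-cell toolchain, which the workflow
names only by its thresholds.

`refine_signature()` drops marker genes whose mean expression in any
non-target major lineage exceeds `max_other_ratio` (default 0.5) times the
target-lineage mean. The underlying exclusion rule ("also highly expressed
in other lineages") is unquantified; 0.5 is this package's choice, exposed
as a parameter.

## 5. Normalisation and signature scoring

`log_normalize()` is library-size normalisation:
`ln(1 + count × 10⁴ / unit_total)`.

`module_score()` follows the binned-control scheme: genes are ranked by
mean expression and cut into `n_bins = 24` equal-frequency bins; for each
signature gene, `n_ctrl = 100` control genes are drawn without replacement
from its bin (capped at the bin's non-signature content); the per-cell
score is mean(signature) − mean(pooled controls). Both defaults are the
upstream tool's, configurable, and the control draw is governed by an
explicit `seed`. One behaviour deserves emphasis: because controls are
matched on *average* expression, a shift that is present in **every** cell
of the dataset is absorbed into the matching (the controls then match the
shifted average) and the score tends to zero. The score estimates the
shift δ only in the realistic regime where markers are elevated in a
subpopulation small enough not to move the gene's global average — the
regime the recovery test uses (2% of cells shifted; mean score within
5% of δ across 20 seeds).

`ssgsea_score()` implements the single-sample GSEA running sum: per
sample, genes are ranked (ties by average rank); walking the list from
highest to lowest expression, the score accumulates the difference between
the weighted in-set empirical CDF (weights `rank^α`, `α = 0.25`) and the
unweighted out-of-set CDF. With `normalize = TRUE` (default) the whole
score matrix is divided by its range. Both defaults match the GSVA
version the workflow names; that package is not a dependency — the
statistic is implemented here and checked against an independently coded
brute-force running sum to 1e-9, along with exact rank-invariance under
strictly increasing per-sample transforms. Gene identifiers are matched
case-insensitively to tolerate symbol-case drift between GMT files and
matrices.

## 6. Survival

`km_estimate()` is the product-limit estimator with Greenwood variance;
censored subjects at an event time remain at risk at that time. With no
censoring it reduces to 1 − ECDF (tested). `logrank_test()` is the
standard unweighted log-rank with hypergeometric variance, vectorised over
distinct times; it is invariant to monotone time transforms and checked
against `survival::survdiff` to 1e-9.

`optimal_cutpoint()` is the maximally selected rank statistic: candidate
cutpoints are midpoints between adjacent distinct score values leaving at
least `minprop = 0.1` of samples on each side; the selected cutpoint
maximises `|O − E|/√V`. The reported p-value is the **naive** log-rank p
at the selected cutpoint — what the cited workflow reports — and is
anti-conservative under the null because of the selection over candidates;
the test suite demonstrates the inflation, and `bonferroni = TRUE` reports
a crude over-candidates upper bound. The search is deterministic.

## 7. The synthetic cohort generator

The generator exists so every downstream stage is testable with no
external data. Its stated world:

* **Samples.** `n_samples` (default 120) samples; cancer type uniform over
  BCC/SCC/CM/AM; stage early/advanced equiprobable (plus optional
  adjacent-normal samples). An ecotype profile is drawn per sample with
  probability proportional to its `stage_bias` weight at that sample's
  stage; subtype proportions follow `Dirichlet(concentration)`; cell
  counts are multinomial with per-sample totals uniform on 500–3000
  (unequal denominators deliberately stress the scaling step).
* **Default profiles** mirror the five archetypes over 44 subtypes in 7
  lineages: four block profiles (T-dominant, stromal, desert, myeloid;
  concentration 50 on the own lineage block, 0.5 elsewhere) and a uniform
  "balanced" profile (concentration 2 everywhere). Stage bias: T-dominant
  0.8 early / 0.2 advanced and desert the reverse — the printed pattern of
  the atlas (its T-cell-dominant ecotype 80% early, desert 76% advanced) —
  with the other three neutral. `block_profiles()` provides the fully
  disjoint well-separated variant used by clustering-recovery tests.
* **QC metrics.** UMIs and genes jointly log-normal with correlation 0.9
  (σ = 0.18 / 0.15 on the log scale — tight enough that
  median − 3 × 1.4826 × MAD is a meaningful positive bound, which is the
  point of the robust filter); housekeeping counts are a binomial thinning
  (p = 0.04) of genes detected; mitochondrial fraction Beta(2, 20) capped
  below the 0.20 gate. A `qc_violation_rate` fraction of cells (default
  2%) receives one planted violation — genes < 200, mito > 0.2, or a
  0.15× low-count outlier — recorded per cell so tests can compare the
  removed set against ground truth.
* **Expression.** Log-normal–Poisson counts; each subtype's disjoint
  marker genes are elevated by `marker_effect` (natural-log fold,
  default 2).
* **Survival.** Exponential event times whose hazard is multiplied by
  `hazard_ratio` when the score exceeds a cutoff; independent exponential
  censoring with rate `base_rate × censor_rate/(1 − censor_rate)`, so the
  marginal censoring fraction is about `censor_rate` under a unit hazard
  ratio.

All generators are governed by a single integer seed (stage-specific seeds
derived deterministically from it) and are byte-identical across reruns.
The generator does **not** emulate realistic full transcriptomes, batch or
platform effects, doublets, ambient RNA, or spatial structure; a green
end-to-end test establishes that the pipeline's statistics behave as
specified under the stated model, not that any biological claim about real
cohorts is reproduced.

## 8. What the end-to-end test asserts, and how its statistic was chosen

The qualitative reproduction test simulates stage-biased cohorts, reruns
QC → composition → scaling → Ward clustering (k = 5), identifies the
desert-like and T-dominant-like ecotypes by dominant lineage share, and
requires, in ≥ 18/20 seeds: positive Pearson residuals for
(desert, advanced) and (T-dominant, early), and a two-sided Wilcoxon
rank-sum on the advanced-stage indicator between the two ecotypes' samples
with `p < 0.05` in the expected direction. The Wilcoxon is applied to
ecotype membership versus stage — a direct test of "the desert-like
ecotype is advanced-enriched" — rather than to per-sample lineage
fractions versus stage, because the latter mixes the three stage-neutral
profiles into both stage groups and tests a different (diluted)
hypothesis. Direction is assessed on advanced-share means, since medians
of a binary indicator tie.

## 9. Numerical and format conventions

* Composition rows sum to 1 to 1e−12; scaled columns have mean 0 / sd 1 to
  1e−9; `ΣR²` matches the chi-square to 1e−9; ssGSEA matches its oracle to
  1e−9.
* Config files are JSON (`jsonlite`); the pipeline funnels all randomness
  through one master seed and writes MD5 digests of every output so reruns
  are verifiable.
* GMT, TSV/CSV, MatrixMarket and Newick are the only I/O formats; all are
  plain text.

## 10. Known limitations

* No doublet detection, ambient-RNA correction, batch integration,
  pseudobulk differential abundance, Cox regression or competing risks —
  all deliberately out of scope.
* The cutpoint p-value is selection-optimistic by construction (see §6);
  treat it as the cited workflow's convention, not a calibrated test.
* The lineage-specificity threshold (`max_other_ratio = 0.5`) and the
  ssGSEA parameters are package choices where the reproduced workflow is
  silent; both are exposed as arguments and recorded in outputs.
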