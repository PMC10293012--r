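---
title: "Stratifying brain tumors by pTRT cell abundance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying brain tumors by pTRT cell abundance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

Potentially tumor-reactive T cells (pTRT cells) are CD8⁺
tumor-infiltrating lymphocytes marked by CXCL13 expression, CD39
positivity with low CCR7, CD103/PD1 co-expression and strong,
tumor-restricted clonal expansion. Brain-metastasis patients split into a
pTRT-high group (these cells above 30% of CD8⁺ TILs) and a pTRT-low group
(below 15%); gliomas are uniformly low. `ptrtkit` implements the
measurement of that fraction on four platforms — single-cell cluster
abundance, a bulk RNA-seq signature score, flow-cytometry gating, and
segmented immunofluorescence tissue — plus the repertoire statistics that
characterize the groups, and combines the per-platform labels into a
consensus call. A synthetic cohort generator with planted ground truth
closes the loop for validation.

## Bulk processing

Sorted-population bulk counts (CD4, CD8, CD45⁻ per patient and
compartment) pass a library-size QC (strictly fewer than 10⁶ total counts
excludes a sample), TMM normalization and log₂-CPM transformation
(`log2((count + 0.5) / (libsize × factor) × 1e6)`).

**Contamination filter.** Sorted T cell profiles from tumors carry
admixed transcripts of transcriptionally hyperactive tumor (CD45⁻) cells.
Per disease group (glioma, BrM) the filter (1) ranks genes by mean
log₂-CPM in CD45⁻ samples and takes the top 250, (2) tests CD45⁻ against
all T cells — blood and tumor pooled, which is what makes contaminated
genes detectable: blood T cells anchor the uncontaminated level —, (3)
keeps genes enriched in CD45⁻ at fold change above 3 and FDR below 0.001,
and (4) removes the per-group intersection of (1) and (3), unioned over
groups. Two conventions the source description leaves open are fixed
here: the FC > 3 cut is applied on the log scale as `log2FC > log2(3)`,
and "highest absolute expression" is read as mean log₂-CPM (not raw
counts), both noted in the function documentation.

**Differential expression.** A deliberate emulation rather than a port of
precision-weighted linear modelling: per-gene two-sample statistics on
log₂-CPM with empirical-Bayes variance moderation. The prior is fitted by
method of moments on `log s²` (the excess of `var(log s²)` over
`trigamma(df/2)` determines the prior degrees of freedom through the
inverse trigamma; no excess gives an infinite-df, fully pooled prior).
Its contract is calibration — on permuted-label null matrices the pass
rate at FC > 2 / FDR < 0.05 stays below the nominal FDR — and recovery of
planted effects, both enforced by tests. Multi-factor designs, batch
covariates and observation-level precision weights are out of scope.

## Signature scores and enrichment

`module_score` follows the binned-control convention: genes are ranked by
average expression into 24 equal-frequency bins and every signature gene
draws 100 control genes (with replacement) from its own bin; the score is
the per-cell signature mean minus the pooled control mean. The defaults
(24/100) are the published defaults of the scoring convention; the seed
that fixes the control draws is an explicit argument. The score is exactly
invariant to global additive shifts and zero on constant input.

`preranked_gsea` computes the weighted Kolmogorov–Smirnov running sum (hit
increments proportional to |statistic|^weight, uniform miss decrements,
score = signed extremum) with gene-label permutation p-values, two-sided
on |ES| with the `(1 + #{|ES_perm| ≥ |ES|}) / (n_perm + 1)` correction, so
p-values are floored at `1/(n_perm+1)` and super-uniform under the null.
Sets outside 15–500 genes after intersection with the ranking are flagged
excluded, not errors. Normalized scores divide by the mean |ES| of
same-sign permutations.

Per-sample set scores are the mean z-score (across samples) of the set
genes — a monotone emulation of sample-level enrichment scoring chosen
because every downstream use only needs a monotone per-sample quantity;
it is validated by group separation and by its correlation with the
measured pTRT fraction, not by equality to any particular GSVA variant.

## Single-cell, TCR, flow, spatial conventions

- Cell QC: mitochondrial fraction strictly below 0.10; feature bounds
  250–3,000 treated as inclusive (the en-dash range is ambiguous; the
  boundary convention is documented and tested).
- Clustering itself is out of scope; the quantification consumes cluster
  labels. Marker selection uses the difference of mean log1p-normalized
  expression (scale factor 10⁴) with the Wilcoxon rank-sum test; with
  count-derived ties the test's normal approximation applies.
- The 15–30% band between the two published cutoffs is returned as
  `indeterminate` instead of being forced into a binary label: the source
  cohort contained no such samples, so any binary rule there would be
  invented. The consensus call treats `indeterminate` as a non-vote.
- Clonotype identity is the CDR3β amino-acid junction alone; V/J calls
  are annotation. Chao1 uses the bias-corrected form everywhere so that
  zero doubletons are well-defined. The five clone-size categories use
  right-closed decade bins at 10⁻⁴ … 10⁻¹ (the category names are
  published, the cutoffs are the repertoire-analysis convention and are
  configurable). Compartment expansion uses a count threshold (≥2 by
  default, configurable and reported), since no numeric rule is published.
- Flow gates are conjunctions of per-marker thresholds on
  arcsinh-transformed intensities (cofactor 150). Manual gate placements
  are not recoverable from any publication; gates are therefore inputs,
  and the simulator emits its own thresholds with ground truth so tests
  are closed-loop.
- The perivascular niche (PVN) is the closed 15-µm expansion of the
  vessel discs — "expanding the vessels by 15 µm" implies a closed
  buffer, so membership is boundary-inclusive. Neighborhoods (20 µm) use
  centroid-to-centroid distances; all distance code is naive O(n²),
  adequate at tissue-section scale and exactly checked against
  brute-force oracles.

## The consensus call

Per patient, each available modality contributes `high`, `low` or
`indeterminate`. Unanimity among informative labels gives the consensus;
any high/low disagreement yields `discordant`; all-indeterminate yields
`insufficient`. The concordance rate is the fraction of patients with at
least two informative modalities whose labels agree — the quantity that
establishes cross-platform reproducibility. The bulk classifier clusters
signature z-scores (Euclidean, complete linkage, k = 2 because the
stratification is two major groups); a singleton cluster triggers a
documented fallback to thresholding the mean z at 0 with a warning. The
"imputed" bulk pTRT frequency is operationalized as the mean signature
z-score, validated through monotone association (Pearson r against the
measured fraction), not as an absolute frequency estimate.

## What the synthetic cohort emulates — and what it does not

The generator's defaults are the study conditions for all validation: 24
patients, glioma:BrM = 1:2, half of BrM patients pTRT-high (assigned as a
stratified count, matching how planned cohorts are described), true pTRT
fractions drawn from Beta distributions truncated to the defining bands
(below 0.15 for low, above 0.30 for high; means ≈ 0.05 and 0.45), a
30-gene signature at log₂FC = 2 in pTRT cells, 20 contamination-only
genes silent in T cells and highly expressed in CD45⁻ profiles admixed at
rate 0.1 into tumor T cell bulk samples, Zipf clone sizes (exponent 1.5,
+0.5 in pTRT-high tumors to reproduce their lower diversity and stronger
expansion, with the top clones absent from matched blood), two-component
log-normal flow intensities with elevated CD39 and reduced CCR7 in pTRT
events, and spatial scenes of 1,500 cells in a 1 mm² window with pTRT
placement at 3:1 odds within 15 µm of one of 8 vessel discs. One master
seed is expanded into independent per-modality substreams so identical
configurations are byte-identical on disk and single modalities can be
regenerated.

Deliberate non-realism, and hence the limits of what passing tests show:
genes are independent negative binomials (no co-expression structure,
no batch effects); per-cell feature counts and mitochondrial fractions
are drawn as QC metadata emulating full-transcriptome statistics, because
the reduced gene universe (1,000 genes) cannot yield realistic detected-
gene counts; flow intensities carry no spillover or acquisition effects;
vessels are discs, not vessel trees; clonotypes are not linked to
individual transcriptomes. Recovery results on this cohort demonstrate
the correctness and calibration of the pipeline's logic, not its
performance on real tissue.

## Numerical choices and problem sizes

Ties in top-N gene selections break lexicographically by gene ID;
classifier label assignment is deterministic with hclust ties resolved by
sample-ID ordering; degenerate inputs (all-identical samples, empty
intersections, units below QC thresholds) raise explicit errors or
flagged exclusions rather than silent results. Oracle-equivalence tests
run on at least 100 randomized small instances per estimator at 10⁻⁹
relative tolerance; calibration uses 100 null matrices of 2,000 genes and
200 random gene sets; parameter recovery uses 20 cohort seeds at the
24-patient default; the Monte-Carlo PVN check uses 10,000 uniform points
against a 2,000² grid quadrature. These sizes keep the full validation
suite under a few minutes on a single CPU while leaving each statistical
assertion comfortably powered.
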