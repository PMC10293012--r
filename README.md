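# ptrtkit

Multiomic stratification of brain tumors by the abundance of potentially
tumor-reactive T cells (pTRT cells).

## The problem

A subset of brain metastases (BrM) — but essentially no gliomas — is heavily
infiltrated by CD8⁺ tumor-infiltrating lymphocytes with hallmarks of tumor
reactivity: CXCL13 expression, CD39 positivity with low CCR7, CD103/PD1
co-expression, exhaustion features and strong, tumor-restricted clonal
expansion. Patients separate cleanly into **pTRT-high** (these cells exceed
30% of CD8⁺ TILs) and **pTRT-low** (below 15%) groups, and the assignment is
reproducible across platforms: single-cell RNA-seq cluster abundance, a bulk
RNA-seq gene-signature score, flow-cytometry gating and multiplexed
immunofluorescence (IF) of tissue sections. `ptrtkit` implements that whole
analysis chain for researchers who want to stratify their own cohorts or
study the statistical behavior of the procedure, together with a synthetic
multi-modal cohort generator with planted ground truth so every stage can be
validated closed-loop without access-restricted patient data.

## What is implemented

- **Bulk RNA-seq of sorted populations** (`qc_min_counts`, `tmm_factors`,
  `log_cpm`, `filter_by_expression`, `dea_two_group`,
  `contamination_filter`, `top_variable_genes`): library QC (samples under
  10⁶ counts dropped), trimmed-mean-of-M-values normalization, log₂ CPM, a
  moderated-t two-group test (gene variances shrunk toward a method-of-
  moments prior, BH-adjusted; pass = |log₂FC| > log₂2 and FDR < 0.05), and
  the four-step tumor-contamination filter: per disease group, intersect the
  250 most highly expressed genes in sorted CD45⁻ (tumor) cells with genes
  enriched in CD45⁻ over all T cells at FC > 3 and FDR < 0.001, then remove
  the union.
- **Signature machinery** (`module_score`, `preranked_gsea`,
  `per_sample_signature_enrichment`): binned-control module scores
  (signature mean minus expression-bin-matched control mean, 24 bins, 100
  controls per gene), weighted Kolmogorov–Smirnov preranked enrichment with
  gene-permutation p-values (sets of 15–500 genes), and a per-sample mean-z
  set score.
- **Single-cell quantification** (`qc_cells`, `cluster_markers`,
  `cluster_abundance`, `classify_by_cluster_fraction`): QC (<10%
  mitochondrial reads, 250–3,000 features), Wilcoxon cluster markers
  (log-FC > 0.25, detected in ≥25% of cluster cells), per-patient pTRT
  cluster fractions and the >30% / <15% high/low rule.
- **TCR repertoire statistics** (`chao1`, `clone_size_categories`,
  `expansion_classes`, `top_expanded_tumor_exclusive`, `morisita_overlap`,
  `match_antigen_db`): bias-corrected Chao1
  `S_obs + f₁(f₁−1)/(2(f₂+1))`, five frequency categories
  (Rare … Hyperexpanded, right-closed decade bins), blood/tumor expansion
  classes, the tumor-exclusivity of the 15 most-expanded clones,
  Morisita–Horn overlap `2Σpq / (Σp² + Σq²)`, and exact CDR3β matching
  against an antigen database at confidence score ≥ 1.
- **Flow cytometry** (`arcsinh_transform`, `qc_and_downsample`,
  `gate_fraction`, `classify_by_gate_fraction`): arcsinh with cofactor 150,
  exclusion of samples under 100 CD8⁺ events, downsampling to 1,500 events,
  conjunctive threshold gates (e.g. CD39⁺CCR7^low) and the >30% rule.
- **Spatial analysis** (`qc_cells_spatial`, `qc_scene`, `vessel_distance`,
  `pvn_membership`, `neighborhood_composition`,
  `nearest_phenotype_distance`): segmented-cell QC (diameter in (4, 12.5)
  µm, detection probability > 0.65, scenes with <30 CD8⁺ cells dropped),
  distance to the nearest vessel boundary, perivascular-niche membership
  (≤15 µm), and 20-µm neighborhood composition.
- **Integration** (`bulk_signature_classifier`, `impute_vs_measured`,
  `consensus_call`, `run_ptrt_pipeline`): hierarchical clustering (Euclidean
  distance, complete linkage, k = 2) of signature z-scores, bulk-score
  versus measured-fraction correlation, and the cross-modality consensus
  call with concordance reporting.
- **Synthetic cohort** (`sim_config`, `simulate_cohort`, `write_cohort`,
  `read_cohort`): matched single-cell counts, sorted bulk profiles with
  planted tumor contamination, Zipf TCR repertoires with tumor-exclusive
  expansion in pTRT-high patients, flow events with CD39/CCR7 mixtures, and
  spatial scenes with perivascular enrichment — all with ground truth and
  deterministic per-modality random streams.

## Worked example

```r
library(ptrtkit)

cohort <- simulate_cohort(sim_config(seed = 1))
cohort
#> ptrt_cohort: 24 patients (8 glioma, 16 BrM; 8 pTRT-high)
#>   sc: 1000 genes x 9600 cells | bulk: 120 samples | clonotypes: 6295
#>   flow events: 96000 | scenes: 24

res <- run_ptrt_pipeline(cohort)
res$consensus
#> ptrt_callset: 24 patients | consensus: high=8, low=16 | concordance 100.0%

head(res$consensus$calls)
#>   patient bulk flow   if   sc n_informative consensus
#> 1     P01 high high high high             4      high
#> 2     P02  low  low  low  low             4       low
#> 3     P03  low  low  low  low             4       low
#> 4     P04 high high high high             4      high
#> 5     P05  low  low  low  low             4       low
#> 6     P06  low  low  low  low             4       low

res$validation$r
#> [1] 0.9821517
```

All 24 patients are called by all four modalities, every multi-modality call
is concordant, the consensus matches the planted labels, and the bulk
signature score tracks the measured single-cell pTRT fraction (r = 0.98) —
the synthetic analogue of the cross-platform agreement the method is built
on.

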