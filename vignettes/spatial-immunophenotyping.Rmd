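---
title: "Spatial immunophenotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immunophenotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialpheno)
library(dplyr)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the
conventions fixed where the underlying methodology left room, and what the
synthetic data can and cannot show.

## The three spatial immunophenotypes

Solid tumors differ not only in how many CD8+ T cells they contain but in
*where* those cells sit. Three archetypes recur across cancers: **inflamed**
tumors with T cells throughout border and center, **excluded** tumors where
T cells accumulate at the invasive border but fail to penetrate the center,
and **ignored** ("cold"/"desert") tumors with hardly any T cells anywhere.
The phenotypes carry distinct prognoses and, crucially, predict response to
anti-PD1 checkpoint inhibition: inflamed tumors respond at far higher rates
than the two cold variants.

## Digital phenotyping from cell tables

### Geometry and densities

The imaging unit is the *stamp*: a 670 × 502 µm field of view
(`stamp_geometry()$area_mm2` = 0.33634 mm²), at least eight of which are
placed at the tumor border (≈50% peritumoral tissue) and center. Cells are
segmented per stamp with marker labels and µm coordinates. The default
density estimate pools all stamps of a region:

$$\hat\lambda = \frac{\text{total cells}}{n_\text{stamps} \times 0.33634\ \text{mm}^2}.$$

The density rule is stated in terms of "median CD8+ T cell density", which
admits two readings: the pooled estimate above (stamps are summarized jointly
per sample) or the median of per-stamp densities. We default to the pooled
estimate — it is the maximum-likelihood intensity under the homogeneous
Poisson model and matches the per-sample summarization of stamp counts —
and expose the per-stamp-median variant via
`cd8_phenotypes(..., method = "stamp_median")`. Samples with fewer than
3 stamps in either region are flagged and never assigned a phenotype.
Densities are computed over tumor + stroma combined for the decision rule
(the rule's thresholds carry no compartment qualifier); compartment-resolved
densities remain available via `compute_densities(by_compartment = TRUE)`.

### The threshold rule and its gaps

With border density $b$, center density $c$ and ratio $r = b/c$:

* inflamed: $b > 200$ cells/mm² and $r < 10$;
* excluded: $b > 200$ and $r > 10$;
* ignored: $b < 150$ and $c < 150$.

Taken literally these predicates are mutually exclusive but not exhaustive:
$b \in [150, 200]$, $b < 150$ with $c \ge 150$, and $r$ exactly 10 fall in
no class. Rather than silently coercing such cases (how the original manual
workflow handled them is not recoverable), `assign_phenotype_digital()`
returns `"unassigned"` with a machine-readable reason
(`threshold_gap`, `ratio_at_cutoff`, `missing_density`). A zero center
density gives $r = +\infty$, the limiting behavior of the rule, so a
populated border over an empty center is excluded. The manual-scoring
analogue (`assign_phenotype_manual()`) needs a quantification of "hardly
any" cells; we default to fewer than 10 cells per region, configurable.

### Nearest-neighbor statistics

`count_neighbors()` and `mean_nearest_distance()` use exact all-pairs
Euclidean distances in 2-D µm coordinates, computed strictly within stamps —
stamps are disjoint fields of view, so cross-stamp distances are undefined.
The radius test is a closed ball (a cell at exactly 10 µm counts); the
reference cell itself is always excluded, including in same-marker
distances. Per-stamp instances are small enough (hundreds of cells) that
exact computation is preferable to spatial indexing; the tests verify both
operations against an independent brute-force double loop.

## The gene classifier

### Gene selection

For each phenotype $p$ a gene is a signature gene when its mean log2
expression beats **each** other phenotype by more than 1 log2 fold-change
and both pairwise tests are significant at BH-adjusted $p < 0.05$. We test
with per-gene Welch two-sample $t$-tests, vectorized over genes, with BH
applied per contrast across all genes. The all-pairwise reading of the
selection rule produces the mutually exclusive tri-block signature
structure; a one-vs-rest alternative exists behind
`select_classifier_genes(contrast = "one_vs_rest")` since the original
contrast design is not recoverable from the methodology text. On log-scale
data the Welch test draws, to first order, the same decision boundary as a
moderated linear-model test, without requiring a fitted prior; the tests
confirm per-gene agreement with `stats::t.test()` and near-complete recovery
of planted markers at the default simulation conditions.

### Centroids, ranks and assignment

Classifier-gene expressions are averaged per phenotype (centroid means) and
rank-transformed within each phenotype's centroid vector — ascending, so
the highest mean gets the highest rank, average ranks for ties. An unknown
sample is correlated (Spearman) against each rank vector and assigned the
arg-max phenotype. Conventions fixed for reproducibility:

* **Correlation target**: raw sample values against centroid ranks. Because
  Spearman's ρ is Pearson on average ranks, value-vs-rank and rank-vs-rank
  are identical; assignments are invariant under any strictly increasing
  transform of a sample (asserted by test), which is what makes the
  classifier transferable across monotone-equivalent normalizations.
* **Rank direction**: ascending; any consistent direction yields identical
  assignments (asserted by test with a flipped model).
* **Ties**: if the top two correlations differ by at most
  `tie_epsilon = 1e-12` (i.e. exact ties at double precision), the sample
  is `unassigned` with reason `correlation_tie` — mirroring the exclusion
  of tied samples in the clinical application of such classifiers — rather
  than broken by ordering.
* **Missing genes**: dropped pairwise per sample; below 50% coverage of the
  classifier genes the sample is `unassigned` (`low_coverage`). The floor is
  deliberately below the ≈75% expressed-gene QC used for degraded RNA
  material, so the pairwise-deletion path is actually exercised.

## Evaluation statistics

* **Confusion metrics.** Sensitivity is diagonal/row-total. Classifier
  performance tables in this literature print a row labelled "specificity"
  that is mathematically the column-wise *precision* (diagonal/column
  total) — every printed value in the transcribed tables matches precision
  and none matches 1 − FPR. `confusion_metrics()` reports it as
  `specificity_paper` next to the conventional `specificity_true`. Zero
  margins yield `NA`, never 0.
* **Accuracy denominators.** The transcribed primary-cohort table's margins
  sum to 42 while its printed total and cohort size are 43, and the printed
  "81%" accuracy equals 35/43 — i.e. one sample without an assignment was
  counted in the denominator. `accuracy(cm, n_total = )` makes that
  denominator explicit; the fixture records the cohort size, and
  `run_paper_fixtures()` reproduces 81% with it (and 83% = 10/12 for the
  metastasis table, whose margins are consistent).
* **Printed precision.** The published tables mix 1- and 2-decimal
  presentation, and at least one entry is truncated rather than rounded
  (6/7 printed as 0.85 while 35/39 rounds to 0.9). Fixture comparisons
  therefore assert agreement to one unit in the last printed decimal — tight
  enough that any single miscounted cell fails, loose enough to accommodate
  the mixed rounding.
* **ROC/AUC.** Thresholds are the midpoints between consecutive distinct
  scores plus ±∞, so tied scores travel along diagonal segments; the
  trapezoidal area then equals the Mann–Whitney statistic with 0.5 credit
  for ties exactly, and `roc_auc()` computes both and asserts equality to
  1e-12. Orientation is explicit: for a score where *lower* values predict
  response (e.g. the excluded gene-set), pass `direction = "lower"`.
* **Logistic odds ratios.** `logistic_or()` fits the univariate logit by
  IRLS (tolerance 1e-10, ≤100 iterations) with a Wald CI on the log scale;
  a slope diverging past |β| > 30 is flagged as separation and reported
  non-converged instead of returning a spuriously huge OR. On a binary
  covariate the OR equals the 2×2 cross-product ratio (13.125 for the
  transcribed response table), which is the closed-form oracle in the
  tests, alongside `stats::glm()`. Whether published gene-set ORs were
  per-unit or per-SD of the score is not stated; both scalings are exposed
  (`scale = "unit"`/`"sd"`).
* **BH adjustment** is the standard step-up with monotonicity enforcement,
  tested against `stats::p.adjust()`.

## TCR repertoire metrics

Skewness is the Gini–Simpson index $1 - \sum_i p_i^2$ over clonotype read
proportions — 0 for a monoclonal repertoire, $1 - 1/K$ for $K$ even
clonotypes — invariant under uniform count scaling. "Diversity" is the
number of *distinct* clonotypes (the quantity plotted in repertoire
comparisons), with total reads reported as a separate field, since the two
phrasings occur interchangeably in methods prose. Clonotype identity is the
provided id column; re-collapsing by CDR3 belongs to the upstream aligner.
The plug-in index is the default; the unbiased finite-sample estimator
$1 - \sum c_i(c_i-1)/(N(N-1))$ is available via `bias_correction = TRUE`
because the variant used by upstream repertoire toolchains is not
documented.

## The synthetic-data generators

The generators define the study conditions under which every downstream
claim is tested:

* **Expression cohorts** (`sim_expression_cohort()`): 30 samples per
  phenotype, 20 marker genes per phenotype with a +2 log2 effect over a
  constant baseline of 5, 500 noise genes, Gaussian noise with sd 1 on the
  log2 scale. Gaussian-on-log2 is a deliberate simplification of
  microarray/RNA-seq noise; the classifier is rank-based, so any
  monotone-equivalent noise model yields the same assignments, and only the
  effect:sd ratio matters. The defaults put the per-contrast Welch $t$ near
  7 at $n = 30$ — comfortably selectable, as real signature genes were — while
  sd 1 keeps individual samples noisy enough that assignment is non-trivial.
* **Cell patterns** (`sim_cell_pattern()`): homogeneous Poisson counts per
  stamp (8 border + 8 center by default) with uniform coordinates; archetype
  CD8 intensities of 400/10 (excluded), 50/30 (ignored) and 400/300
  (inflamed) cells/mm² at border/center, chosen to sit well inside each
  decision region so that threshold assignment recovers the archetype in
  ≥95% of seeds. The declared stamp layout travels with the table as an
  attribute so empty stamps are not lost.
* **Repertoires** (`sim_tcr_repertoire()`): symmetric Dirichlet proportions
  (concentration ≪ 1 gives clonal skew) with multinomial read sampling;
  zero-read clonotypes are dropped with a message.
* **Response labels** (`sim_response_labels()`): Bernoulli draws at the
  observed trial rates — 6/10 responders among inflamed, 4/39 among
  excluded + ignored — so that the end-to-end experiment's NPV/PPV converge
  to 35/39 ≈ 0.90 and 0.60.

Every generator takes an explicit seed and restores the global RNG state
(`withr::with_seed`); reruns are bit-identical.

What the synthetic data does **not** emulate: cross-platform transfer
(microarray-trained, RNA-seq-assigned classification), batch structure,
spatial inhomogeneity within stamps, compartment-dependent intensities, or
correlated gene-gene noise. Passing tests therefore demonstrate the
correctness of the algorithms and the internal consistency of the pipeline
under the stated model — not the classifier's real-data accuracy, which was
established on clinical cohorts that require controlled access. The
synthetic held-out accuracy (≈1.0 at effect 2, sd 1) is accordingly higher
than the 81%/83% achieved on real cohorts, and the synthetic gene-set AUCs
exceed the ≈0.72–0.75 observed in trial data.

## Problem sizes and runtime

The test-suite and acceptance-script experiment sizes are chosen as the
smallest that make each claim statistically meaningful: 20
discovery/validation replicates of 90 + 90 samples for classifier recovery;
≥300 held-out samples for the null (chance-level) binomial check at
α = 0.01; ≥100 seeded stamp patterns for archetype recovery; 3000 samples
for NPV/PPV convergence (binomial SE ≈ 0.012 on PPV at that size, well
inside the ±0.05 band); 1000 random instances for each closed-form oracle
equivalence (AUC vs pair counting, Spearman vs Pearson-on-ranks, both to
1e-12).

## Interfaces

All stages read and write plain-text tables (TSV expression matrices with a
`gene_id` column, CSV cell tables, TSV clonotype tables, TSV serialized
classifiers mirroring the role of a published classifier-gene supplement);
see `?spatialpheno-io`. Configuration is ordinary function arguments with
the published thresholds as defaults (200/150 cells/mm², ratio 10, 10 µm
radius, 1 logFC, α = 0.05), so sensitivity analyses are one-argument
changes; the exported functions `run_synthetic_benchmark()`,
`run_paper_fixtures()` and `run_response_experiment()` are the pipeline
entry points.

## Known limitations

* The density rule's gap handling (`unassigned`) is our convention; the
  original workflow asserts all scans fell inside the three classes, so the
  gaps may simply never have occurred in practice.
* Wald CIs for the logistic OR are anti-conservative in small samples
  (profile-likelihood CIs are not implemented).
* DeLong CIs for AUC, survival analysis, deconvolution and pathway analysis
  are out of scope.
* The per-stamp-median density variant changes assignments for samples with
  strongly heterogeneous stamps; only the pooled default is exercised by the
  recovery guarantees.
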