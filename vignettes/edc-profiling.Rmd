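---
title: "Phenotypic profiling of endocrine-disruptor effects in dopaminergic neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic profiling of endocrine-disruptor effects in dopaminergic neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edcprofiler)
```

## The biological question

Endocrine-disrupting chemicals such as bisphenols (BPA, BPS) and
perfluoroalkyls (PFOS, PFOA) are suspected of altering the phenotype of
midbrain dopaminergic neurons at sub-cytotoxic concentrations — changes in
α-synuclein and tyrosine-hydroxylase (TH) levels, and in neurite outgrowth
and branching, rather than outright cell death. High-content imaging can
detect such subtle, multi-dimensional shifts: neurons are stained for DNA
(Hoechst), TH, α-synuclein and the dendrite marker MAP2, imaged per well of
a 384-well plate, and every cell is reduced to a standardized vector of
morphological and intensity features. Statistics and machine learning then
ask whether treated wells are distinguishable from vehicle controls, and
along which feature axes.

This package implements that analysis end to end. Since no microscope data
can ship with it, a parametric image generator plays the microscope; all
its defaults were fixed from the physical constants and population ranges
below **before** any downstream result was inspected, and they define the
study conditions for the reproduction tests.

## The synthetic plate

`build_plate_layout()` places conditions on non-edge wells (rows B–O,
columns 2–23) of a 384-well plate: 4 compounds × 4 doses (0.01, 0.1, 1,
2 µM) × 3 wells plus 12 vehicle wells — 60 wells, at least 12 per
classification class. Edge wells are excluded as in real screens
(evaporation artifacts). Wells alternate between two simulated biological
replicates.

`generate_field()` renders a 256 × 256 px field at 0.1628 µm/px with:

- **Living neurons**: elliptical nuclei (areas well above 2000 px) with dim
  DNA staining (mean ≈ 700–1000 counts), a soma, and 2–4 MAP2-positive
  neurites grown as biased random walks with stochastic branching; 85% of
  cells are TH-positive, with cytoplasmic TH and a brighter membrane rim.
- **Apoptotic cells**: small, bright pyknotic nuclei (area below 2000 px,
  DNA mean ≥ 2600), no soma or neurites — a fixed ~6% of cells, so
  viability itself carries no treatment signal by design.
- **Optics**: a constant background (~200 counts) with a ±15% linear
  illumination gradient, Poisson shot noise and Gaussian read noise
  (σ = 25), clipped to the 16-bit range.
- **Hierarchy of variation**: lognormal multipliers at replicate (3%), well
  (2%) and cell (12%) level.

Treatment acts through `default_effect_model()`: a saturating dose response
(25/50/80/100% of the maximal effect over the four doses) on five axes —
α-synuclein up (bisphenols ×1.6, perfluoroalkyls ×1.35 at saturation), TH
cytoplasm/membrane up (stronger for perfluoroalkyls), neurite length and
branching down to 0.65–0.75×. The two chemical classes thus share
signatures within class but differ between classes, which is what the
profiling stage should rediscover.

Every cell's ground truth (position, nucleus area, rendered mean
intensities, neurite skeleton length, branch count, viability) is returned,
enabling oracle tests of the segmentation.

**Realism and limits.** The generator reproduces the statistical structure
that the analysis exploits — compartmentalized stains, population mixtures,
dose-coupled multipliers, plate-level nuisance variation — but not optical
physics: there is no point-spread function, no chromatic aberration, no
focus drift, and cells do not overlap (placement enforces a minimum
separation). Absolute feature values are therefore arbitrary; only
contrasts between conditions are meaningful, which is also how the real
assay is interpreted.

## Segmentation

`segment_field()` performs, per field:

1. **Illumination correction** — a quadratic background surface is fitted
   to block-wise low quantiles (with one robust refit) and subtracted.
2. **Nuclei** — fixed intensity threshold (350 counts; `"otsu"` available
   as a per-image policy), watershed splitting on the distance transform,
   and a debris filter (≥ 80 px).
3. **Viability** — a nucleus is a living cell iff its area is **strictly
   greater than 2000 px** (≈ 53 µm² at 0.1628 µm/px) **and** its mean DNA
   intensity is **strictly below 1500**; condensed bright nuclei are
   apoptotic and take no further part in per-cell features.
4. **Cells** — the MAP2-positive area is partitioned among living nuclei by
   seeded propagation (geodesic Voronoi), capped at 120 px from a seed.
5. **Compartments** — cytoplasm(L) = cell(L) \ nucleus(L);
   membrane(L) = cell(L) \ erode(cell(L), city-block radius 5), i.e. a
   5-px ≈ 0.81 µm rim inside the cell edge.
6. **Neurites** — soma cores are removed by a morphological opening
   (disc radius 8 px) of the MAP2 mask; the remainder is thinned to a 1-px
   skeleton (Zhang–Suen, compiled), spur-pruned (3 px); length sums
   inter-pixel steps (1 or √2) × pixel pitch; branch points are skeleton
   pixels with ≥ 3 neighbours, adjacent ones counted once; skeleton pixels
   are attributed to cells via the cell labels beneath them.

## The 126-feature catalogue

`feature_catalogue()` pins the feature space as data
(`inst/extdata/feature_catalogue.csv`): 48 intensity features (4
compartments × 3 stain channels × mean/median/SD/integrated), 20 shape
features (4 compartments × area, perimeter, eccentricity, solidity, form
factor), 24 texture features (gray-level co-occurrence matrices at
distance 1 over 4 directions, 16 levels between the 1st and 99th intensity
percentile; ASM, contrast, correlation, homogeneity — for TH, α-synuclein
and MAP2 on cell and cytoplasm), and 34 context features (channel
correlations, counts and densities, nearest-neighbour distances, neurite
morphometry, TH/α-synuclein composites). Per-cell features are averaged
over living cells, context features over fields, giving exactly one
126-vector per well — the unit of all downstream analysis.

## Profiling, classification, statistics

- **Profiling**: features are robust-scaled ((x − median)/IQR), wells are
  median-aggregated per condition, and conditions are clustered by cosine
  distance (1 − cos) with average linkage; the dendrogram is exported as
  Newick. Control and top-dose wells are embedded in 2-D (UMAP,
  single-threaded for reproducibility, or PCA) with a silhouette
  diagnostic.
- **Classification**: treated vs control with three kinds — linear
  discriminant analysis, level-wise boosted trees, and leaf-wise
  (`grow_policy = "lossguide"`) boosted trees. Stratified 90/10 split,
  exhaustive grid search scored by 5-fold CV, 10-fold CV of the winner,
  held-out confusion matrix (accuracy = (TN+TP)/total) and normalized
  feature importances (absolute standardized coefficients for LDA, gain
  for trees). Scaling parameters are fitted on the training split only.
- **Dose–response**: features are divided by the per-plate control mean,
  then per feature × compound a one-way ANOVA over vehicle + doses gates
  Tukey-HSD dose-vs-vehicle contrasts, starred at the 0.05/0.01/0.001
  tiers.

## Problem sizes

The defaults target a desk-scale study on one CPU: 60 wells × 4 fields ×
256 px ≈ 90 s for the full pipeline, and the 5-seed reproduction study
(`acceptance_study()`, also exposed as `scripts/acceptance.R`) in under
10 min. These sizes were chosen so that the classification design still has
≥ 12 wells per class and ≥ 2 wells per (compound, dose) group for the
ANOVA, i.e. the statistical structure of a full screen survives the
shrinking. `fields_per_well = 16` and larger images restore
screening-scale wells at proportional cost.

```{r, eval = FALSE}
res <- run_pipeline(small_config(), seed = 1L)
sapply(res$classification, `[[`, "accuracy")
res$clustering$leaf_order
head(res$dose_response)
```
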