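---
title: "Neighborhood enrichment and proximity analysis of spatial niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighborhood enrichment and proximity analysis of spatial niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichekit)
```

# Scope and data model

`nichekit` analyses imaging-based spatial transcriptomics of the CosMx
SMI kind: a raw genes × cells transcript count matrix plus per-cell
centroid coordinates, acquired tile by tile as fields of view (FOVs).
The central container, `CosmxExperiment`, extends
`SingleCellExperiment`: the `counts` assay holds raw non-negative
integer counts; `colData` carries `fov`, local and global coordinates,
and an optional cell-type `label`; `metadata()$fov_offsets` records
each tile's global origin.

Two conventions are fixed and documented rather than configurable:
global coordinates are `(FOV origin + local centroid) × scale`,
Cartesian with y increasing upward; and cell identifiers are composite
(`f<fov>_c<cell>`), since vendor exports only guarantee uniqueness of
`cell_ID` within a FOV. The export format does not declare its
coordinate unit, so `readCosmx(coordinateScale=)` is an explicit knob
(default 1, i.e. "already µm"). This matters because the proximity
analysis uses an absolute 20 µm threshold: with pixel-unit exports the
caller must supply the conversion.

# Quality control

Two filters mirror standard practice for the two data kinds.

* **Droplet scRNA-seq** (`filterScrnaCells`): a cell is removed iff
  total transcripts < 500, detected genes < 100, or mitochondrial
  fraction > 0.10. The inequalities are strict, so cells exactly at a
  threshold are retained. A zero-count cell has no defined
  mitochondrial fraction; it is removed under the transcript rule and
  the fraction is treated as 0, never as a division error. The
  mitochondrial gene set is caller-supplied (default: `MT-` prefix)
  because panel annotations vary. The report attributes each removed
  cell to *every* rule it violates, so rule counts can overlap.
* **In situ panels** (`filterCosmxCells`): control probes (features
  named `Neg*` or `System*`) are removed *first*, then cells with
  fewer than 20 remaining counts. The order is deliberate and fixed:
  control-probe signal is non-biological and must not rescue a cell
  over the count threshold.

Both filters are idempotent and act per cell, so removing one cell can
never change another's verdict.

# Marker gating

Cell subsets are defined by boolean conjunctions over raw counts: a
cell carries a label iff every required marker has count ≥ the
positivity threshold (default 1, i.e. any detected transcript — the
minimal reading of "cells expressing" a marker; the threshold is
per-rule configurable for robustness analyses). The builtin vocabulary
covers the five populations of the motivating analysis: IL-36G+
keratinocytes (IL36G), Treg (CD4, FOXP3, IL2RA), Th17 (CD4, IL17A,
RORC), regTh17 (IL17F, IL26, FOXP3), NKT (CD8A, NKG7, KLRD1).

Gates are independent, not a partition: nothing prevents a cell from
satisfying both the Treg and Th17 conjunctions, and downstream
proximity analysis treats a multi-gated cell as a member of each
subset. Gating operates on raw counts; this is an assumption (counts
in situ are already comparable across cells of similar size), and the
threshold knob is the handle for sensitivity checks. Marker names are
matched after upper-casing and hyphen stripping, since panels and
prose spell markers differently (IL-17F vs IL17F).

# Neighborhood enrichment

For each cell, its k nearest neighbors (default k = 150) by Euclidean
distance *within its own FOV* — tiles are imaged independently and
stitched neighborhoods would cross physical gaps. Distances come from
a per-FOV all-pairs distance matrix in base R; at tile scale (≤ a few
thousand cells) this is exact and fast, and sidesteps approximate
spatial indexing entirely. Ties at the k-th distance are broken by
ascending cell id for determinism. FOVs with fewer than k+1 cells
contribute all their n−1 neighbors rather than being discarded, which
would silently bias composition; a singleton FOV yields an empty
neighbor set with a warning.

Neighbor-type counts are tabulated sparsely per focal cell and
aggregated across FOVs, then condensed into the sender × receiver
matrix in four steps: (i) types with fewer than 20 total cells (across
all FOVs — the threshold is a dataset total, not per-FOV) are excluded
from both axes; (ii) counts are summed within sender groups; (iii)
each column is divided by the total number of cells of that receiver
type — its "potential neighbors" — in the analysed dataset; (iv) rows
are rescaled to sum to 100. Step (iii) is the abundance correction
that makes a rare but specifically co-localized receiver visible; it
is the only reading of the normalization consistent with rows summing
to a fixed total, and a flag (`abundanceNormalize = FALSE`) disables
it to emit raw composition percentages instead, since both variants
are plausible inputs to a published heatmap. Significance of a single
entry is assessed against a label-permutation null
(`enrichmentPermutationTest`): labels are shuffled across cells with
the neighbor graph fixed, preserving composition, and the add-one
empirical p-value is reported.

# Proximity analysis

For each immune cell, the Euclidean distance to the nearest target
cell (default target: IL-36G+ keratinocytes), stratified Near
(< 20 µm, strict) / Far (≥ 20 µm). The default scope restricts targets
to the query's FOV, consistent with the neighborhood analysis;
`scope = "global"` is available. A query that is itself a target is
matched to the nearest *other* target, and queries in FOVs without
targets get NA with a warning and are excluded downstream.

Subset pairs are compared with two-sided Wilcoxon rank-sum tests on
their distance distributions. When both groups have ≤ 20 observations
the p-value is exact: the standard exact distribution without ties,
otherwise full enumeration over rank assignments (feasible at those
sizes, and it handles midranks). Larger samples use the tie-corrected
normal approximation with continuity correction. Which quantities the
original analyses compared is underdetermined; the package commits to
distance distributions as the primary comparison and emits a Fisher
2×2 Near/Far test per pair as a sensitivity output, claiming
replication of neither specific p-value. No multiplicity correction is
applied by default (none is standard for a single planned contrast);
`adjust = "BH"` adds Benjamini–Hochberg.

# Per-type expression summaries

`summarizePanel` reports mean, median and total raw transcript counts
per (gene, cell type) for an 8-gene panel (CD3E, CD4, CTLA4, FOXP3,
IL17A, IL17F, IL26, IL36G by default). Raw counts, not normalized
values, are summarised — the table is the contract; plotting is left
to the caller.

# The synthetic generator

`generateSpatial` emulates exactly the features the analyses consume:
multi-FOV µm coordinates, type labels, raw counts for the builtin
marker panel plus housekeeping genes and Neg/System control probes,
and a planted co-localization. Design choices, in the package's own
words:

* **Abundances are exact per-FOV counts**, not Poisson expectations:
  deterministic composition keeps the 20-cell exclusion rule and
  subset sample sizes exactly at their nominal values. The default
  tile is 500 × 500 µm with 300 cells (60 anchors, 4 × 40 immune, 80
  background) — a realistic in-tissue density (~1.2 × 10³ cells/mm²).
* **Counts are negative binomial** (the field-standard overdispersed
  choice) with type-specific means: own-gate markers mean 12,
  dispersion 3; off-type markers 0.01; housekeeping 3; control probes
  0.05. Under this model a planted subset cell passes its 3-marker
  gate with probability (1 − (3/15)³)³ ≈ 0.976 ≥ 0.95, and
  off-subset cells pass a foreign gate with probability ≪ 0.05.
* **Niches**: anchors are a uniform (homogeneous Poisson-like) point
  process; for each niche spec the configured fraction of the
  attracted subset is placed uniformly in a disk of the given radius
  around a random same-FOV anchor, clipped to the tile (clipping can
  only shorten the anchor distance, so a radius-15 niche is always
  within the 20 µm Near band). The default plants 80 % of regTh17
  cells within 15 µm of IL36G_KC anchors.
* **Determinism**: the RNG seed is part of the config; identical
  configs give bit-identical datasets and byte-identical flat files,
  and generation never perturbs the caller's RNG stream.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real tissue: segmentation errors and
doublets, spatially varying density and tissue morphology (epidermis
vs dermis layering), the 1,000-plex panel (it carries ~27 features),
ambient/background spill beyond flat control probes, and
patient-to-patient variability. Recovery of a planted niche shows the
statistics are implemented correctly and are powered at desk scale; it
is not evidence about any particular tissue.

`generateCountMatrix` builds the droplet-QC fixture: background cells
parameterised far from every threshold (total ≈ 1390, ~265 genes,
~3 % mito, low dispersion), plus cells constructed to violate exactly
one rule each (360 transcripts across 120 genes; 800 across 80 genes;
20 % mitochondrial at 600 transcripts) and boundary cells at exactly
500 / 100 / 10 %, which the strict filter must retain.

# Numerical choices

* k-NN ties: ascending cell id. Distances: exact all-pairs per FOV.
* Nearest-target distances use the squared-cross-distance identity
  with clamping of tiny negative values from cancellation.
* Matrix CSVs serialise doubles at `%.17g`, so write → read is
  bit-identical; integer matrices return as numeric.
* Empirical permutation p-values use the add-one estimator
  `(1 + #(null ≥ obs)) / (1 + nPerm)`, never exactly zero.
* Degenerate inputs are structured errors (`nichekit_error_*` condition
  classes) or warnings with defined fallbacks: empty matrices, all
  features control probes, FOVs without targets, singleton FOVs.

# Problem sizes in the test suite

The suite validates at desk scale, chosen for statistical adequacy:
oracle-equivalence against an independent brute-force implementation
on 20 random datasets of 50–500 cells; planted-niche recovery on
4-FOV datasets (~1,200 cells) with k = 10 and a 99-permutation null —
a configuration at which the permutation test rejects at p ≤ 0.01
across seeds while the per-test cost stays in seconds; null
calibration over 50 single-FOV replicates, pooling all six pairwise
rank-sum p-values per replicate into one Kolmogorov–Smirnov test
against U(0,1) (pairs within a replicate share samples and are weakly
dependent; at these sizes the pooled check remains well calibrated).

# Known limitations

* The enrichment matrix is descriptive; only the single-entry
  permutation test attaches uncertainty, and it conditions on the
  observed composition and graph.
* Within-FOV restriction means cells near tile borders have truncated
  neighborhoods; no edge correction is applied (none is standard for
  this statistic).
* Gating on raw counts ignores cell size and segmentation quality;
  the positivity threshold is the only lever exposed.
* The reader targets the flat-file dialect described above; other
  export layouts (e.g. wide polygon formats) are carried as opaque
  extras, not interpreted.
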