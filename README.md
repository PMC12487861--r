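# nichekit

Cellular-niche analysis for imaging-based spatial transcriptomics
(CosMx SMI-style flat-file exports), written for skin-immunology studies
that ask *which cell types surround which, and how close are specific
immune subsets to a target epithelial population?* The motivating use
case is inflammatory skin disease, where hybrid regulatory/Th17
("regTh17") lymphocytes gated as IL17F+IL26+FOXP3+ co-localize with
IL-36G+ keratinocytes — but every stage is generic over marker panels
and cell-type vocabularies.

The package provides, as composable Bioconductor-style functions around
a `SingleCellExperiment`-derived `CosmxExperiment` container:

* **Flat-file IO** — `readCosmx()` / `writeCosmx()` for the
  `exprMat_file` / `metadata_file` / `fov_positions_file` (+ optional
  `polygons`, `tx_file`) dialect, with per-FOV origin stitching
  (`global = origin + local`, scaled to µm).
* **QC filters** — `filterScrnaCells()` removes cells with < 500
  transcripts, < 100 detected genes, or > 10 % mitochondrial fraction
  (strict inequalities; boundary cells retained);
  `filterCosmxCells()` drops `Neg*`/`System*` control probes first,
  then cells with < 20 counts.
* **Marker gating** — `gateCells()` applies boolean AND-rules
  (`builtinRules()`: IL36G_KC, Treg, Th17, regTh17, NKT); gates are
  independent, so cells may carry several labels.
* **Neighborhood enrichment** — for each cell, its k = 150 (default)
  nearest within-FOV neighbors; neighbor-type counts are summed per
  sender type, normalized by each receiver type's total abundance, and
  row-rescaled, yielding a sender × receiver percentage matrix whose
  rows sum to 100. Types with < 20 total cells are excluded.
  `enrichmentPermutationTest()` provides a label-permutation null.
* **Proximity analysis** — `proximityAnalysis()` computes each immune
  cell's Euclidean distance to the nearest target cell, stratifies
  Near (< 20 µm) / Far (≥ 20 µm), and `compareSubsets()` runs two-sided
  Wilcoxon rank-sum tests (exact for small samples) between subsets.
* **Expression summaries** — `summarizePanel()`: per (gene, cell type)
  mean / median / total raw transcript counts for an 8-gene panel
  (CD3E, CD4, CTLA4, FOXP3, IL17A, IL17F, IL26, IL36G) by default.
* **Synthetic data** — `generateSpatial()` builds deterministic
  multi-FOV datasets with negative-binomial marker counts, control
  probes, and *planted niches* (a configurable fraction of one subset
  placed within a radius of another), so the whole pipeline is testable
  without any external download; `generateCountMatrix()` plants exact
  QC-rule violations for filter auditing.
* **Pipeline driver** — `runPipeline()` chains
  simulate/read → QC → gate → enrich → proximity → summarize from an
  INI-style config, writing stage CSVs and a JSON run manifest; a thin
  CLI wrapper lives at `inst/scripts/nichekit-pipeline.R`.

## The statistic at the core

For sender type *s* and receiver type *r*, with `N_c(r)` the number of
type-*r* cells among cell *c*'s k nearest within-FOV neighbors and
`n_r` the total number of type-*r* cells:

```
raw[s, r]  = Σ_{c : type(c) = s} N_c(r)
norm[s, r] = raw[s, r] / n_r
E[s, r]    = 100 · norm[s, r] / Σ_r' norm[s, r']
```

Division by `n_r` corrects for receiver abundance (a ubiquitous type
would otherwise dominate every neighborhood); the row rescaling makes
rows comparable as percentages summing to 100. Under complete spatial
randomness every entry of a row is ≈ 100/(number of types); planted
co-localization lifts the corresponding entry above its
label-permutation null.

## Worked example

```r
library(nichekit)
gs <- generateSpatial(simConfig(seed = 7, nFovs = 4))   # planted regTh17 niche
ds <- filterCosmxCells(gs$dataset)$dataset
gr <- gateCells(ds)

em <- neighborhoodEnrichment(ds, k = 10, minCellsPerType = 20)
round(em, 1)
#>           receiver
#> sender     IL36G_KC  NKT Other regTh17 Th17 Treg
#>   IL36G_KC     15.8 16.3  15.0    20.7 16.1 16.1
#>   NKT          18.1 16.6  15.7    16.2 16.8 16.6
#>   Other        16.3 15.5  16.5    17.6 17.0 17.1
#>   regTh17      20.1 14.3  15.6    18.5 15.2 16.3
#>   Th17         17.7 16.5  17.7    17.2 15.0 16.0
#>   Treg         16.7 16.5  17.0    17.3 16.2 16.2
```

Every row sums to 100. The regTh17 row peaks in the IL36G_KC column
(20.1 vs a ≈ 16.7 baseline): regTh17 neighborhoods are enriched for
IL-36G+ keratinocytes, as planted. A label-permutation null makes that
quantitative:

```r
nb <- knnWithinFov(ds, k = 10)
enrichmentPermutationTest(nb, cellLabels(ds), "regTh17", "IL36G_KC",
                          nPerm = 99, seed = 1)$p_value
#> [1] 0.01
```

Proximity stratification tells the same story per cell:

```r
prox <- proximityAnalysis(ds, gr)        # distance to nearest IL36G_KC
subsetProportions(prox)
#>    subset prop_near prop_far   n
#> 1    Treg     0.270    0.730 159
#> 2    Th17     0.282    0.718 156
#> 3 regTh17     0.849    0.151 152
#> 4     NKT     0.287    0.713 157
compareSubsets(prox, "regTh17", "Treg")$p_value
#> [1] 1.054139e-24
```

84.9 % of gated regTh17 cells lie within 20 µm of an IL-36G+
keratinocyte, against ≈ 28 % for the other three subsets; the rank-sum
test on the distance distributions is decisive.

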