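test_that("the generator is deterministic and produces a valid dataset", {
  g1 <- generateSpatial(simConfig(seed = 99))
  g2 <- generateSpatial(simConfig(seed = 99))
  expect_identical(SummarizedExperiment::assay(g1$dataset),
                   SummarizedExperiment::assay(g2$dataset))
  expect_identical(spatialCoords(g1$dataset), spatialCoords(g2$dataset))
  expect_identical(g1$truth, g2$truth)
  expect_true(methods::validObject(g1$dataset))
  ## flat files written from the same dataset are byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCosmx(g1$dataset, d1, gzip = FALSE)
  writeCosmx(g2$dataset, d2, gzip = FALSE)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## generator RNG does not leak into the caller's stream
  set.seed(5); before <- runif(1)
  set.seed(5); generateSpatial(simConfig(seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated flat files round-trip through the reader", {
  gs <- generateSpatial(simConfig(seed = 17))
  dir <- withr::local_tempdir()
  writeCosmx(gs$dataset, dir)   # gzip on: exercises the compressed path
  back <- readCosmx(dir)
  ord <- colnames(gs$dataset)
  expect_identical(sort(colnames(back)), sort(ord))
  expect_equal(spatialCoords(back)[ord, ], spatialCoords(gs$dataset))
  expect_equal(SummarizedExperiment::assay(back)[, ord],
               SummarizedExperiment::assay(gs$dataset))
  expect_identical(cellLabels(back)[ord], cellLabels(gs$dataset))
  expect_equal(fovOffsets(back), fovOffsets(gs$dataset))
})

test_that("planted subsets pass their gates; off-subset cells do not", {
  hits <- 0; tot <- 0; false_pos <- 0; neg_tot <- 0
  for (s in 1:3) {
    gs <- generateSpatial(simConfig(seed = 200 + s))
    gr <- gateCells(gs$dataset)
    truth <- gs$truth
    for (ty in c("Treg", "Th17", "regTh17", "NKT", "IL36G_KC")) {
      planted <- truth$cell_id[truth$label == ty]
      hits <- hits + sum(gr$assignments[planted, ty])
      tot <- tot + length(planted)
      ## off-subset false positive rate vs a foreign gate
      neg <- truth$cell_id[truth$label == "Other"]
      false_pos <- false_pos + sum(gr$assignments[neg, ty])
      neg_tot <- neg_tot + length(neg)
    }
  }
  expect_gte(hits / tot, 0.95)
  expect_lte(false_pos / neg_tot, 0.05)
})

test_that("full attraction at 15 um forces Near proportions above 0.9", {
  for (s in 1:3) {
    cfg <- simConfig(seed = 300 + s,
                     niches = list(list(subset = "regTh17",
                                        anchor = "IL36G_KC",
                                        radius = 15, fraction = 1)))
    gs <- generateSpatial(cfg)
    truth <- gs$truth
    ## independent geometric check: planted distance to the recorded anchor
    reg <- truth[truth$label == "regTh17", ]
    expect_true(all(reg$in_niche))
    xy <- spatialCoords(gs$dataset)
    d_anchor <- sqrt(rowSums((xy[reg$cell_id, ] - xy[reg$anchor_id, ])^2))
    expect_true(all(d_anchor <= 15 + 1e-9))
    ## and via the proximity module on ground-truth labels
    lab <- cellLabels(gs$dataset)
    tab <- proximityAnalysis(gs$dataset, lab, subsets = "regTh17")
    expect_gt(subsetProportions(tab)$prop_near, 0.9)
  }
})

test_that("no attraction yields comparable Near proportions across subsets", {
  gs <- generateSpatial(simConfig(seed = 404, niches = list()))
  lab <- cellLabels(gs$dataset)
  tab <- suppressWarnings(proximityAnalysis(gs$dataset, lab))
  pr <- subsetProportions(tab)
  ## all four uniform subsets should sit in a similar Near band
  expect_lt(diff(range(pr$prop_near)), 0.25)
})

test_that("over-dense configurations are rejected up front", {
  err <- tryCatch(
    simConfig(seed = 1, fovSize = c(20, 20),
              abundances = c(IL36G_KC = 500, regTh17 = 500)),
    condition = identity)
  expect_s3_class(err, "nichekit_error_too_dense")
  err2 <- tryCatch(
    simConfig(seed = 1, niches = list(list(subset = "regTh17",
                                           anchor = "Missing",
                                           radius = 10, fraction = 0.5))),
    condition = identity)
  expect_s3_class(err2, "nichekit_error_bad_config")
})

test_that("toy count matrices plant QC violations exactly", {
  m <- generateCountMatrix(100, seed = 8, plantLowTranscripts = 5,
                           plantLowGenes = 3, plantHighMito = 2,
                           plantBoundary = 2)
  planted <- attr(m, "planted")
  res <- filterScrnaCells(m)
  expect_setequal(res$report$removed_ids,
                  c(planted$low_transcripts, planted$low_genes,
                    planted$high_mito))
  expect_setequal(res$report$removed_by_rule$min_transcripts,
                  planted$low_transcripts)
  expect_setequal(res$report$removed_by_rule$min_genes, planted$low_genes)
  expect_setequal(res$report$removed_by_rule$max_mito, planted$high_mito)
  ## boundary cells sit exactly on every threshold and are retained
  for (b in planted$boundary) {
    expect_equal(sum(m[, b]), 500)
    expect_equal(sum(m[, b] > 0), 100)
    expect_equal(sum(m[startsWith(rownames(m), "MT-"), b]) / sum(m[, b]), 0.1)
    expect_true(b %in% colnames(res$counts))
  }
  ## determinism
  m2 <- generateCountMatrix(100, seed = 8, plantLowTranscripts = 5,
                            plantLowGenes = 3, plantHighMito = 2,
                            plantBoundary = 2)
  expect_identical(m, m2)
  ## silent mitochondrial profile -> nothing removed by the mito rule
  m0 <- generateCountMatrix(50, seed = 9, mitoFraction = 0)
  expect_equal(sum(m0[startsWith(rownames(m0), "MT-"), ]), 0)
  expect_length(filterScrnaCells(m0)$report$removed_by_rule$max_mito, 0)
})
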