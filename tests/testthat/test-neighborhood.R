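test_that("k-NN on collinear cells matches hand-computed neighbors", {
  ## cells at x = 0, 1, 3 in one FOV
  ce <- make_ce(x = c(0, 1, 3), y = c(0, 0, 0), ids = c("a", "b", "c"))
  nb <- knnWithinFov(ce, k = 1)
  expect_identical(nb$neighbors, list(a = "b", b = "a", c = "b"))
  ## saturation: k >= n - 1 returns all other same-FOV cells
  nb2 <- knnWithinFov(ce, k = 10)
  expect_setequal(nb2$neighbors$a, c("b", "c"))
  expect_equal(unname(lengths(nb2$neighbors)), c(2, 2, 2))
})

test_that("neighbors never cross FOV boundaries even when tiles interleave", {
  ## global coordinates of the two FOVs overlap completely
  ce <- make_ce(x = c(0, 1, 0.2, 1.2), y = c(0, 0, 0, 0),
                fov = c("1", "1", "2", "2"),
                ids = c("a1", "a2", "b1", "b2"),
                offsets = data.frame(fov = c("1", "2"),
                                     x_offset = 0, y_offset = 0))
  nb <- knnWithinFov(ce, k = 3)
  expect_identical(nb$neighbors$a1, "a2")   # b1 at distance 0.2 is ignored
  expect_identical(nb$neighbors$b1, "b2")
})

test_that("ties at the k-th distance break by ascending cell id", {
  ce <- make_ce(x = c(0, 1, -1), y = c(0, 0, 0), ids = c("m", "z", "a"))
  nb <- knnWithinFov(ce, k = 1)
  expect_identical(nb$neighbors$m, "a")  # both at distance 1; id "a" < "z"
})

test_that("a singleton FOV yields an empty neighbor set with a warning", {
  ce <- make_ce(x = c(0, 1, 5), y = c(0, 0, 0), fov = c("1", "1", "2"),
                ids = c("a", "b", "solo"),
                offsets = data.frame(fov = c("1", "2"), x_offset = 0,
                                     y_offset = 0))
  expect_warning(nb <- knnWithinFov(ce, k = 2), class = "nichekit_warning")
  expect_length(nb$neighbors$solo, 0)
})

test_that("neighbor-type tabulation counts labels per focal cell", {
  ce <- make_ce(x = c(0, 1, 2, 3, 10, 11), y = rep(0, 6),
                ids = letters[1:6],
                label = c("A", "A", "B", "A", "B", "B"))
  nb <- knnWithinFov(ce, k = 3)
  prof <- tabulateNeighborTypes(nb, cellLabels(ce))
  ## focal a: neighbors b, c, d -> {A:2, B:1}
  expect_equal(as.numeric(prof["a", c("A", "B")]), c(2, 1))
  ## focal f: neighbors e, d, c (hand check distances 1, 7, 8... within k=3)
  bf <- bf_knn(ce, 3)
  for (cid in letters[1:6]) {
    expect_setequal(nb$neighbors[[cid]], bf[[cid]])
    tab <- table(cellLabels(ce)[bf[[cid]]])
    expect_equal(as.numeric(prof[cid, names(tab)]), as.numeric(tab))
  }
  ## homogeneous neighborhood gives a single nonzero entry
  expect_equal(sum(prof["f", ] > 0) <= 2, TRUE)
})

test_that("unlabelled neighbors are dropped with a warning or rejected", {
  lab <- c(a = "A", b = NA, c = "A")
  ce <- make_ce(x = 1:3, y = rep(0, 3), ids = c("a", "b", "c"), label = lab)
  nb <- knnWithinFov(ce, k = 2)
  expect_warning(prof <- tabulateNeighborTypes(nb, lab),
                 class = "nichekit_warning_unlabeled_neighbor")
  expect_equal(as.numeric(prof["a", "A"]), 1)  # b dropped
  expect_error(tabulateNeighborTypes(nb, lab, unlabeled = "error"),
               class = "nichekit_error_unlabeled_neighbor")
})

test_that("a single sender/receiver type yields the row [100]", {
  ce <- make_ce(x = runif(25, 0, 10), y = runif(25, 0, 10),
                label = rep("A", 25))
  em <- neighborhoodEnrichment(ce, k = 5, minCellsPerType = 20)
  expect_equal(dim(em), c(1, 1))
  expect_equal(unname(em[1, 1]), 100)
})

test_that("types under the min-cell threshold are excluded from both axes", {
  set.seed(77)
  lab <- c(rep("A", 25), rep("B", 25), rep("C", 10))
  ce <- make_ce(x = runif(60, 0, 100), y = runif(60, 0, 100), label = lab)
  em <- neighborhoodEnrichment(ce, k = 5, minCellsPerType = 20)
  expect_setequal(rownames(em), c("A", "B"))
  expect_setequal(colnames(em), c("A", "B"))
  expect_true("C" %in% attr(em, "excluded"))
  ## all labels excluded -> structured error
  expect_error(neighborhoodEnrichment(ce, k = 5, minCellsPerType = 100),
               class = "nichekit_error_all_types_excluded")
})

test_that("pipeline equals the brute-force reference on random datasets", {
  set.seed(123)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    k <- sample(1:8, 1)
    ce <- random_ce(n, n_types = sample(2:4, 1))
    labels <- cellLabels(ce)
    em <- neighborhoodEnrichment(ce, labels, k = k, minCellsPerType = 5)
    bf <- bf_enrichment(ce, labels, k = k, min_cells = 5)
    expect_equal(em[rownames(bf), colnames(bf)], bf,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("retained rows sum to 100 and shuffling cell order changes nothing", {
  set.seed(9)
  ce <- random_ce(150, n_types = 3)
  em <- neighborhoodEnrichment(ce, k = 10, minCellsPerType = 10)
  expect_equal(unname(rowSums(em)), rep(100, nrow(em)), tolerance = 1e-6)
  perm <- sample(ncol(ce))
  cep <- ce[, perm]
  emp <- neighborhoodEnrichment(cep, cellLabels(cep), k = 10,
                                minCellsPerType = 10)
  expect_equal(emp, em, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("raw composition mode skips receiver-abundance correction", {
  set.seed(13)
  ce <- random_ce(80, n_types = 2)
  raw <- neighborhoodEnrichment(ce, k = 5, minCellsPerType = 5,
                                abundanceNormalize = FALSE)
  expect_equal(unname(rowSums(raw)), rep(100, nrow(raw)), tolerance = 1e-6)
  ## in raw mode the entries are neighborhood composition percentages, so a
  ## type twice as abundant roughly doubles its column share
  expect_false(isTRUE(all.equal(raw,
    neighborhoodEnrichment(ce, k = 5, minCellsPerType = 5))))
})

test_that("planted niche is recovered against a label-permutation null", {
  gs <- generateSpatial(planted_config(seed = 21, nFovs = 4))
  ds <- filterCosmxCells(gs$dataset)$dataset
  nb <- knnWithinFov(ds, k = 10)
  pt <- enrichmentPermutationTest(nb, cellLabels(ds), "regTh17", "IL36G_KC",
                                  nPerm = 99, seed = 22)
  expect_lt(pt$p_value, 0.05)
  expect_gt(pt$observed, mean(pt$null))
})
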