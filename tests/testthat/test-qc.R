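## A tiny matrix where each cell's totals/genes/mito are set by hand.
toy_counts <- function() {
  ## genes: 250 ordinary + 50 mito-prefixed
  genes <- c(paste0("G", 1:250), paste0("MT-", 1:50))
  build <- function(n_genes, per_gene, n_mito = 0, mito_per = 0) {
    v <- integer(300)
    v[seq_len(n_genes)] <- per_gene
    if (n_mito > 0) v[250 + seq_len(n_mito)] <- mito_per
    v
  }
  m <- cbind(
    good   = build(150, 4),                 # 600 tx, 150 genes, 0% mito
    low_tx = build(200, 2, 10, 9),          # 400+90=490 tx, 210 genes, 18%? no:
    exact  = build(90, 5, 10, 5),           # 500 tx, 100 genes, 10% mito
    himito = build(150, 4, 10, 8))          # 680 tx, 160 genes, 80/680 mito
  rownames(m) <- genes
  m
}

test_that("scRNA filter applies the three rules with strict boundaries", {
  m <- toy_counts()
  res <- filterScrnaCells(m)
  rep_ <- res$report
  ## low_tx: 490 < 500 -> removed by transcripts only (210 genes, 90/490=18% mito
  ## also > 10%, so it is attributed to both rules it violates)
  expect_true("low_tx" %in% rep_$removed_by_rule$min_transcripts)
  ## exact boundary cell: exactly 500 tx, 100 genes, 10.0% mito -> retained
  expect_true("exact" %in% colnames(res$counts))
  ## himito: 80/680 = 11.8% > 10% -> removed by mito rule only
  expect_equal(rep_$removed_by_rule$max_mito,
               c("low_tx", "himito")[c("low_tx", "himito") %in%
                                       rep_$removed_by_rule$max_mito])
  expect_true("himito" %in% rep_$removed_by_rule$max_mito)
  expect_false("himito" %in% rep_$removed_by_rule$min_transcripts)
  expect_true("good" %in% colnames(res$counts))
  ## reconciliation
  expect_equal(rep_$n_retained + length(rep_$removed_ids), rep_$n_input)
})

test_that("three-cell toy attributes removals to the right rules", {
  ## cells: (600 tx/150 genes/5% mito), (499/150/5%), (600/150/11%)
  genes <- c(paste0("G", 1:200), paste0("MT-", 1:20))
  cell <- function(tx_non_mito, n_genes, mito) {
    v <- integer(220)
    per <- tx_non_mito / n_genes
    v[seq_len(n_genes)] <- per
    v[200 + 1] <- mito
    v
  }
  m <- cbind(c1 = cell(570, 150, 30),   # 600 total, 30/600 = 5%
             c2 = cell(474.05, 149, 25), # ~499 total
             c3 = cell(534, 150, 66))   # 600 total, 11% mito
  ## make c2 exact: 474 over 149 genes is fractional; construct directly
  m[, "c2"] <- 0
  m[seq_len(149), "c2"] <- c(rep(4L, 27), rep(3L, 122)) # 108+366=474
  m[201, "c2"] <- 25                                    # total 499, 5% mito
  rownames(m) <- genes
  expect_equal(sum(m[, "c2"]), 499)
  res <- filterScrnaCells(m)
  expect_identical(colnames(res$counts), "c1")
  expect_equal(unname(res$report$n_removed_by_rule["min_transcripts"]), 1L)
  expect_equal(unname(res$report$n_removed_by_rule["max_mito"]), 1L)
  expect_equal(unname(res$report$n_removed_by_rule["min_genes"]), 0L)
})

test_that("zero-count cells fall under the transcript rule, not a division error", {
  m <- matrix(0L, nrow = 120, ncol = 2,
              dimnames = list(c(paste0("G", 1:110), paste0("MT-", 1:10)),
                              c("empty", "ok")))
  m[, "ok"] <- 5L
  expect_no_error(res <- filterScrnaCells(m, thresholds = qcThresholds(
    minTranscripts = 10, minGenes = 10)))
  expect_true("empty" %in% res$report$removed_by_rule$min_transcripts)
  expect_false("empty" %in% res$report$removed_by_rule$max_mito)
})

test_that("empty matrices are a structured error", {
  err <- tryCatch(filterScrnaCells(matrix(0L, 0, 0)), condition = identity)
  expect_s3_class(err, "nichekit_error_empty_matrix")
})

test_that("filtering is idempotent and per-cell independent", {
  set.seed(11)
  m <- generateCountMatrix(60, seed = 11, plantLowTranscripts = 3,
                           plantHighMito = 2)
  r1 <- filterScrnaCells(m)
  r2 <- filterScrnaCells(r1$counts)
  expect_identical(r2$counts, r1$counts)
  expect_equal(length(r2$report$removed_ids), 0)
  ## dropping any one cell leaves every other verdict unchanged
  drop <- sample(colnames(m), 5)
  for (d in drop) {
    rd <- filterScrnaCells(m[, setdiff(colnames(m), d), drop = FALSE])
    expect_identical(rd$report$removed_ids,
                     setdiff(r1$report$removed_ids, d))
  }
})

test_that("CosMx filter removes control probes first, then low-count cells", {
  genes <- c("IL17F", "IL36G", "NegPrb1", "SystemCtl3")
  ## probe counts must not rescue a cell: 25 total with 10 on Neg -> 15 -> removed
  cnt <- matrix(c(20L, 0L, 0L, 0L,   # cell a: 20 biological -> retained
                  19L, 0L, 5L, 0L,   # cell b: 19 biological -> removed
                  10L, 5L, 10L, 0L), # cell c: 15 biological of 25 -> removed
                nrow = 4, dimnames = list(genes, NULL))
  cells <- data.frame(id = c("a", "b", "c"), fov = "1",
                      x = c(0, 1, 2), y = 0)
  ce <- CosmxExperiment(cnt, cells,
                        data.frame(fov = "1", x_offset = 0, y_offset = 0))
  res <- filterCosmxCells(ce)
  expect_identical(rownames(res$dataset), c("IL17F", "IL36G"))
  expect_identical(colnames(res$dataset), "a")
  expect_identical(res$report$removed_ids, c("b", "c"))
  expect_equal(res$report$n_genes_removed, 2)

  ## all features controls -> structured error
  ce2 <- CosmxExperiment(
    matrix(5L, 2, 3, dimnames = list(c("NegPrb1", "SystemCtl1"), NULL)),
    cells, data.frame(fov = "1", x_offset = 0, y_offset = 0))
  err <- tryCatch(filterCosmxCells(ce2), condition = identity)
  expect_s3_class(err, "nichekit_error_all_genes_removed")
})

test_that("QC report serializes as key-value plus id list", {
  m <- generateCountMatrix(30, seed = 5, plantLowGenes = 2)
  rep_ <- filterScrnaCells(m)$report
  p <- withr::local_tempfile(fileext = ".txt")
  writeQcReport(rep_, p)
  kv <- readLines(p)
  expect_true(any(grepl("^n_input = 30$", kv)))
  expect_identical(readLines(paste0(p, ".removed_ids.txt")),
                   rep_$removed_ids)
})
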