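#' Cell-level quality-control thresholds
#'
#' Bundles the QC cut-offs used by \code{\link{filterScrnaCells}} and
#' \code{\link{filterCosmxCells}}. Boundary semantics are strict: a cell
#' is removed for \emph{fewer than} \code{minTranscripts} transcripts,
#' \emph{fewer than} \code{minGenes} detected genes, or \emph{more than}
#' \code{maxMitoFraction} mitochondrial fraction, so cells sitting exactly
#' on a threshold are retained. Likewise the in situ panel filter removes
#' cells with \emph{fewer than} \code{minCosmxCounts} total counts
#' (computed after control-probe removal).
#'
#' @param minTranscripts Minimum per-cell transcript total (default 500).
#' @param minGenes Minimum detected genes per cell (default 100).
#' @param maxMitoFraction Maximum mitochondrial fraction (default 0.10).
#' @param minCosmxCounts Minimum post-probe-removal counts for in situ
#'   panels (default 20).
#' @param controlPrefixes Feature-name prefixes identifying non-biological
#'   control probes (default \code{c("Neg", "System")}).
#' @return A validated list of class \code{QcThresholds}.
#' @export
qcThresholds <- function(minTranscripts = 500, minGenes = 100,
                         maxMitoFraction = 0.10, minCosmxCounts = 20,
                         controlPrefixes = c("Neg", "System")) {
  stopifnot(minTranscripts >= 0, minGenes >= 0, minCosmxCounts >= 0,
            maxMitoFraction >= 0, maxMitoFraction <= 1)
  structure(list(minTranscripts = minTranscripts, minGenes = minGenes,
                 maxMitoFraction = maxMitoFraction,
                 minCosmxCounts = minCosmxCounts,
                 controlPrefixes = controlPrefixes),
            class = "QcThresholds")
}

qc_report <- function(n_input, removed_by_rule, all_ids) {
  removed_ids <- sort(unique(unlist(removed_by_rule, use.names = FALSE)))
  structure(list(
    n_input = n_input,
    n_removed_by_rule = vapply(removed_by_rule, length, integer(1)),
    n_retained = n_input - length(removed_ids),
    removed_ids = removed_ids,
    removed_by_rule = removed_by_rule), class = "QcReport")
}

#' @export
print.QcReport <- function(x, ...) {
  cat(sprintf("QC report: %d cells in, %d retained, %d removed\n",
              x$n_input, x$n_retained, x$n_input - x$n_retained))
  for (r in names(x$n_removed_by_rule))
    cat(sprintf("  %-16s %d\n", r, x$n_removed_by_rule[[r]]))
  invisible(x)
}

#' Filter scRNA-seq cells on transcripts, genes and mitochondrial load
#'
#' Removes low-quality cells from a raw genes x cells count matrix: a cell
#' is removed iff its transcript total is below \code{minTranscripts}, its
#' number of detected genes is below \code{minGenes}, or its mitochondrial
#' fraction exceeds \code{maxMitoFraction}. Cells with zero total counts
#' have no defined mitochondrial fraction and are removed under the
#' transcript rule. The report attributes every removed cell to each rule
#' it violates, so the per-rule counts can exceed the number of distinct
#' removed cells.
#'
#' @param counts Raw genes x cells count matrix with rownames (gene names)
#'   and colnames (cell ids).
#' @param mitoGenes Mitochondrial gene set: either a character vector of
#'   gene names or a predicate \code{function(gene_names) -> logical}.
#'   Default: names starting \code{"MT-"}.
#' @param thresholds A \code{\link{qcThresholds}} object.
#' @return List with \code{counts} (the filtered matrix) and \code{report}
#'   (a \code{QcReport}).
#' @examples
#' m <- matrix(rpois(600, 8), nrow = 6,
#'             dimnames = list(c(paste0("G", 1:5), "MT-CO1"), paste0("c", 1:100)))
#' res <- filterScrnaCells(m, thresholds = qcThresholds(minTranscripts = 10))
#' res$report
#' @export
filterScrnaCells <- function(counts,
                             mitoGenes = function(g) startsWith(g, "MT-"),
                             thresholds = qcThresholds()) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0)
    nk_error("empty_matrix", "count matrix has no genes or no cells")
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  th <- thresholds
  ids <- colnames(counts)
  mito <- if (is.function(mitoGenes)) mitoGenes(rownames(counts))
          else rownames(counts) %in% mitoGenes
  totals <- col_totals(counts)
  ngenes <- col_totals(counts > 0)
  mito_counts <- if (any(mito)) col_totals(counts[mito, , drop = FALSE])
                 else rep(0, ncol(counts))
  mito_frac <- ifelse(totals > 0, mito_counts / totals, 0)

  viol <- list(
    min_transcripts = ids[totals < th$minTranscripts],
    min_genes       = ids[ngenes < th$minGenes],
    max_mito        = ids[mito_frac > th$maxMitoFraction])
  rep_ <- qc_report(ncol(counts), viol, ids)
  keep <- !(ids %in% rep_$removed_ids)
  list(counts = counts[, keep, drop = FALSE], report = rep_)
}

#' Filter an in situ panel dataset: control probes, then low-count cells
#'
#' Preprocessing for CosMx-style data in a fixed, documented order:
#' (1) features whose name starts with any control prefix (negative
#' probes, system probes) are dropped; (2) cells whose total count,
#' computed \emph{after} probe removal, falls below
#' \code{minCosmxCounts} are dropped. Probes are removed first because
#' control-probe signal is not biological and should not rescue a cell
#' over the count threshold.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param thresholds A \code{\link{qcThresholds}} object.
#' @return List with \code{dataset} (filtered \code{CosmxExperiment}) and
#'   \code{report} (a \code{QcReport}; gene removals recorded in
#'   \code{report$n_genes_removed}).
#' @export
filterCosmxCells <- function(x, thresholds = qcThresholds()) {
  th <- thresholds
  genes <- rownames(x)
  is_ctrl <- Reduce(`|`, lapply(th$controlPrefixes,
                                function(p) startsWith(genes, p)),
                    accumulate = FALSE, init = rep(FALSE, length(genes)))
  if (all(is_ctrl))
    nk_error("all_genes_removed",
             "all features match a control-probe prefix; nothing left to analyse")
  y <- x[!is_ctrl, ]
  totals <- col_totals(SummarizedExperiment::assay(y, "counts"))
  ids <- colnames(y)
  viol <- list(min_counts = ids[totals < th$minCosmxCounts])
  rep_ <- qc_report(ncol(y), viol, ids)
  rep_$n_genes_removed <- sum(is_ctrl)
  rep_$removed_genes <- genes[is_ctrl]
  keep <- !(ids %in% rep_$removed_ids)
  list(dataset = y[, keep], report = rep_)
}

#' Serialize a QC report
#'
#' Writes the report as a flat \code{key = value} text file plus a
#' companion \code{<path>.removed_ids.txt} with one removed cell id per
#' line.
#'
#' @param report A \code{QcReport}.
#' @param path Output path for the key-value file.
#' @return \code{path}, invisibly.
#' @export
writeQcReport <- function(report, path) {
  lines <- c(paste0("n_input = ", report$n_input),
             paste0("n_retained = ", report$n_retained),
             vapply(names(report$n_removed_by_rule), function(r)
               paste0("removed_", r, " = ", report$n_removed_by_rule[[r]]),
               character(1)))
  if (!is.null(report$n_genes_removed))
    lines <- c(lines, paste0("n_genes_removed = ", report$n_genes_removed))
  writeLines(lines, path)
  writeLines(report$removed_ids, paste0(path, ".removed_ids.txt"))
  invisible(path)
}
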