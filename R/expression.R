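#' Default gene panel for per-cell-type expression summaries
#'
#' The 8 T-cell/keratinocyte genes of interest summarised by
#' \code{\link{summarizePanel}}: CD3E, CD4, CTLA4, FOXP3, IL17A, IL17F,
#' IL26, IL36G.
#'
#' @return Character vector of 8 gene names.
#' @export
defaultPanel <- function() {
  c("CD3E", "CD4", "CTLA4", "FOXP3", "IL17A", "IL17F", "IL26", "IL36G")
}

#' Per-cell-type summary of raw transcript counts for a gene panel
#'
#' For every (gene, cell type) pair: the mean transcript count per cell,
#' the median transcript count per cell, the total transcript count
#' across all cells of that type, and the number of cells. Raw counts are
#' summarised (no normalisation). Panel names are matched after
#' normalization (\code{IL-36G} matches \code{IL36G}).
#'
#' @param x A \linkS4class{CosmxExperiment} (or genes x cells count
#'   matrix).
#' @param labels Named label vector, cell id -> cell type (default
#'   \code{cellLabels(x)}); unlabelled cells are excluded.
#' @param panel Genes to summarise (default \code{\link{defaultPanel}()}).
#' @return Tidy data.frame: \code{gene}, \code{cell_type},
#'   \code{mean_count}, \code{median_count}, \code{total_count},
#'   \code{n_cells}.
#' @examples
#' gs <- generateSpatial(simConfig(seed = 1))
#' head(summarizePanel(gs$dataset, cellLabels(gs$dataset)))
#' @export
summarizePanel <- function(x, labels = NULL, panel = defaultPanel()) {
  counts <- if (is(x, "CosmxExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  if (is.null(labels) && is(x, "CosmxExperiment")) labels <- cellLabels(x)
  if (is.null(labels))
    nk_error("no_labels", "per-type summary requires cell labels")
  idx <- match_markers(panel, rownames(counts))
  if (anyNA(idx))
    nk_error("missing_marker",
             paste0("panel gene(s) absent from dataset: ",
                    paste(panel[is.na(idx)], collapse = ", ")),
             markers = panel[is.na(idx)])
  labels <- labels[intersect(names(labels), colnames(counts))]
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0)
    nk_error("no_labels", "no labelled cells to summarise")
  types <- sort(unique(labels))
  sub <- as.matrix(counts[idx, names(labels), drop = FALSE])
  rownames(sub) <- panel
  res <- do.call(rbind, lapply(panel, function(g) {
    do.call(rbind, lapply(types, function(ty) {
      v <- sub[g, labels == ty]
      data.frame(gene = g, cell_type = ty,
                 mean_count = mean(v), median_count = median(v),
                 total_count = sum(v), n_cells = length(v))
    }))
  }))
  rownames(res) <- NULL
  res
}
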