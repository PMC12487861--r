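#' CosmxExperiment: multi-FOV spatial transcriptomics container
#'
#' An S4 container for imaging-based spatial transcriptomics data of the
#' kind exported as CosMx SMI flat files: a genes x cells raw transcript
#' count matrix together with per-cell spatial coordinates. It extends
#' \linkS4class{SingleCellExperiment}; the \code{counts} assay holds raw
#' non-negative integer counts, \code{colData} carries per-cell fields
#' \code{fov}, \code{x_local}, \code{y_local}, \code{x}, \code{y} (global,
#' micrometres) and optionally \code{label} (cell-type annotation), and
#' \code{metadata(x)$fov_offsets} records the global origin of each field
#' of view (FOV).
#'
#' Global coordinates follow the convention
#' \code{global = (FOV origin + local) * coordinate scale}, Cartesian with
#' y increasing upward. Validity requires unique cell identifiers,
#' non-negative integral counts, finite coordinates, and that every cell's
#' FOV appears in the offset table.
#'
#' @slot int_elementMetadata,int_colData,int_metadata inherited machinery.
#'
#' @seealso \code{\link{readCosmx}}, \code{\link{generateSpatial}}
#' @aliases CosmxExperiment-class
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @export
setClass("CosmxExperiment", contains = "SingleCellExperiment")

setValidity("CosmxExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is_count_like(m))
      msg <- c(msg, "'counts' must be non-negative and integral")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("fov", "x", "y")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  ids <- colnames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "cell identifiers (colnames) must be present and unique")
  off <- S4Vectors::metadata(object)$fov_offsets
  if (is.null(off) || !is.data.frame(off) ||
      !all(c("fov", "x_offset", "y_offset") %in% colnames(off)))
    msg <- c(msg,
      "metadata 'fov_offsets' must be a data.frame with fov, x_offset, y_offset")
  else if (all(need %in% colnames(cd)) &&
           !all(as.character(cd$fov) %in% as.character(off$fov)))
    msg <- c(msg, "every cell's fov must appear in fov_offsets")
  if (all(c("x", "y") %in% colnames(cd)) &&
      (!all(is.finite(cd$x)) || !all(is.finite(cd$y))))
    msg <- c(msg, "cell coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CosmxExperiment
#'
#' @param counts genes x cells matrix of raw transcript counts
#'   (non-negative integers; dense or \pkg{Matrix} sparse). Must carry
#'   rownames (gene names); colnames, if present, must equal
#'   \code{cells$id}.
#' @param cells data.frame with one row per cell and columns \code{id}
#'   (unique), \code{fov}, \code{x}, \code{y} (global coordinates, um);
#'   optional \code{x_local}, \code{y_local}, \code{label}.
#' @param fovOffsets data.frame with columns \code{fov}, \code{x_offset},
#'   \code{y_offset} giving each FOV's global origin in um.
#' @param extras named list of opaque extra tables (e.g. parsed polygon or
#'   transcript-location files); stored in \code{metadata(x)$extras}.
#'
#' @return A \linkS4class{CosmxExperiment}.
#' @examples
#' cells <- data.frame(id = c("a", "b"), fov = 1, x = c(0, 3), y = c(0, 4))
#' cnt <- matrix(c(1L, 0L, 2L, 5L), nrow = 2,
#'               dimnames = list(c("IL36G", "CD4"), NULL))
#' off <- data.frame(fov = 1, x_offset = 0, y_offset = 0)
#' ce <- CosmxExperiment(cnt, cells, off)
#' @export
CosmxExperiment <- function(counts, cells, fovOffsets, extras = list()) {
  if (!is.data.frame(cells) || !all(c("id", "fov", "x", "y") %in% names(cells)))
    nk_error("bad_cells", "'cells' needs columns id, fov, x, y")
  if (anyDuplicated(cells$id))
    nk_error("duplicate_ids", paste0(
      "duplicate cell ids: ",
      paste(unique(cells$id[duplicated(cells$id)]), collapse = ", ")))
  if (ncol(counts) != nrow(cells))
    nk_error("dim_mismatch", sprintf(
      "counts has %d columns but %d cell records", ncol(counts), nrow(cells)))
  if (!is.null(colnames(counts)) && !identical(colnames(counts), as.character(cells$id)))
    nk_error("dim_mismatch", "counts colnames disagree with cells$id")
  colnames(counts) <- as.character(cells$id)
  cd <- S4Vectors::DataFrame(cells[setdiff(names(cells), "id")],
                             row.names = as.character(cells$id))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  S4Vectors::metadata(sce)$fov_offsets <- as.data.frame(fovOffsets)
  S4Vectors::metadata(sce)$extras <- extras
  new("CosmxExperiment", sce)
}

#' Accessors for CosmxExperiment
#'
#' \code{fovs} returns the per-cell FOV identifier; \code{spatialCoords}
#' the global-um coordinate matrix (columns x, y; rownames cell ids);
#' \code{cellLabels} the per-cell type annotation (NA where unlabelled);
#' \code{fovOffsets} the FOV origin table.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param value Replacement label vector (length = number of cells, or a
#'   named vector keyed by cell id).
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("fovs", "CosmxExperiment", function(x)
  as.character(SummarizedExperiment::colData(x)$fov))

#' @rdname accessors
#' @export
setMethod("spatialCoords", "CosmxExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  m <- cbind(x = cd$x, y = cd$y)
  rownames(m) <- colnames(x)
  m
})

#' @rdname accessors
#' @export
setMethod("cellLabels", "CosmxExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"label" %in% colnames(cd)) return(setNames(rep(NA_character_, ncol(x)),
                                                  colnames(x)))
  setNames(as.character(cd$label), colnames(x))
})

#' @rdname accessors
#' @export
setMethod("cellLabels<-", "CosmxExperiment", function(x, value) {
  if (!is.null(names(value))) value <- value[colnames(x)]
  if (length(value) != ncol(x))
    nk_error("bad_labels", "label vector length must equal number of cells")
  SummarizedExperiment::colData(x)$label <- as.character(value)
  x
})

#' @rdname accessors
#' @export
setMethod("fovOffsets", "CosmxExperiment", function(x)
  S4Vectors::metadata(x)$fov_offsets)

#' @importMethodsFrom methods show
setMethod("show", "CosmxExperiment", function(object) {
  cat("class: CosmxExperiment\n")
  cat(sprintf("dim: %d genes x %d cells\n", nrow(object), ncol(object)))
  f <- fovs(object)
  cat(sprintf("FOVs: %d (%s)\n", length(unique(f)),
              paste(utils::head(sort(unique(f)), 6), collapse = ", ")))
  lab <- cellLabels(object)
  if (any(!is.na(lab))) {
    tab <- sort(table(lab), decreasing = TRUE)
    cat(sprintf("labels: %d types; top: %s\n", length(tab),
                paste(utils::head(names(tab), 4), collapse = ", ")))
  } else cat("labels: none\n")
  invisible(NULL)
})
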