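## CosMx SMI flat-file dialect: gzip (or plain) CSVs exported per run,
## cells-as-rows with `fov` and `cell_ID` key columns.
##   exprMat_file.csv.gz       fov, cell_ID, <gene>...
##   metadata_file.csv.gz      fov, cell_ID, CenterX_local_px, CenterY_local_px
##                             [, cell_type]
##   fov_positions_file.csv.gz fov, x_global_px, y_global_px
##   polygons.csv.gz, tx_file.csv.gz   optional; carried as opaque extras.

.flat_files <- c(exprMat = "exprMat_file", metadata = "metadata_file",
                 fov_positions = "fov_positions_file",
                 polygons = "polygons", tx = "tx_file")

find_flat_file <- function(directory, stem) {
  for (ext in c(".csv.gz", ".csv")) {
    p <- file.path(directory, paste0(stem, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

read_flat_csv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  read.csv(con, check.names = FALSE, stringsAsFactors = FALSE)
}

## Composite cell id, stable across files: cell_ID is unique within a FOV.
.cell_id <- function(fov, cell) paste0("f", fov, "_c", cell)

#' Read a CosMx-style flat-file directory
#'
#' Parses the flat-file set exported by the CosMx SMI AtoMX platform (or
#' emulated by \code{\link{writeCosmx}}): an expression matrix, a cell
#' metadata table with local centroid coordinates, and an FOV-positions
#' table with global tile origins. Optional polygon and
#' transcript-location files are parsed if present and carried as opaque
#' extras. Global per-cell coordinates are computed as
#' \code{(FOV origin + local centroid) * coordinateScale}.
#'
#' @param directory Path containing the flat files (\code{.csv.gz} or
#'   plain \code{.csv}).
#' @param coordinateScale Micrometres per coordinate unit. The default 1
#'   assumes the export is already in um; set this when coordinates are in
#'   pixels, since downstream distance thresholds (e.g. the 20 um Near/Far
#'   cut) are in um.
#'
#' @return A \linkS4class{CosmxExperiment}.
#' @examples
#' dir <- system.file("extdata", "cosmx_mini", package = "nichekit")
#' ce <- readCosmx(dir)
#' ce
#' @export
readCosmx <- function(directory, coordinateScale = 1) {
  if (!dir.exists(directory))
    nk_error("missing_file", paste0("directory not found: ", directory))
  paths <- vapply(.flat_files, function(s) find_flat_file(directory, s),
                  character(1))
  mandatory <- c("exprMat", "metadata", "fov_positions")
  miss <- mandatory[is.na(paths[mandatory])]
  if (length(miss))
    nk_error("missing_file",
             paste0("missing mandatory flat file(s): ",
                    paste(.flat_files[miss], collapse = ", ")),
             files = unname(.flat_files[miss]))

  expr <- read_flat_csv(paths[["exprMat"]])
  meta <- read_flat_csv(paths[["metadata"]])
  fpos <- read_flat_csv(paths[["fov_positions"]])

  if (!all(c("fov", "cell_ID") %in% names(expr)))
    nk_error("bad_format",
             "expression matrix lacks 'fov'/'cell_ID' key columns; unrecognised dialect")
  if (!all(c("fov", "cell_ID", "CenterX_local_px", "CenterY_local_px") %in%
           names(meta)))
    nk_error("bad_format", "metadata file lacks required columns")
  if (!all(c("fov", "x_global_px", "y_global_px") %in% names(fpos)))
    nk_error("bad_format", "fov positions file lacks required columns")

  expr_ids <- .cell_id(expr$fov, expr$cell_ID)
  meta_ids <- .cell_id(meta$fov, meta$cell_ID)
  orphans <- setdiff(meta_ids, expr_ids)
  if (length(orphans))
    nk_error("orphan_cells",
             paste0("cells present in metadata but absent from expression matrix: ",
                    paste(orphans, collapse = ", ")),
             orphan_ids = orphans)
  uncoord <- setdiff(expr_ids, meta_ids)
  if (length(uncoord))
    nk_error("orphan_cells",
             paste0("cells present in expression matrix but absent from metadata: ",
                    paste(uncoord, collapse = ", ")),
             orphan_ids = uncoord)

  genes <- setdiff(names(expr), c("fov", "cell_ID"))
  counts <- t(as.matrix(expr[, genes, drop = FALSE]))
  storage.mode(counts) <- "integer"
  rownames(counts) <- genes
  colnames(counts) <- expr_ids

  ## align metadata to expression order
  meta <- meta[match(expr_ids, meta_ids), , drop = FALSE]
  off <- data.frame(fov = as.character(fpos$fov),
                    x_offset = fpos$x_global_px * coordinateScale,
                    y_offset = fpos$y_global_px * coordinateScale)
  oi <- match(as.character(meta$fov), off$fov)
  if (anyNA(oi))
    nk_error("missing_fov",
             paste0("FOV(s) without an entry in fov positions: ",
                    paste(unique(meta$fov[is.na(oi)]), collapse = ", ")))

  cells <- data.frame(
    id = expr_ids,
    fov = as.character(meta$fov),
    x_local = meta$CenterX_local_px * coordinateScale,
    y_local = meta$CenterY_local_px * coordinateScale,
    x = off$x_offset[oi] + meta$CenterX_local_px * coordinateScale,
    y = off$y_offset[oi] + meta$CenterY_local_px * coordinateScale,
    stringsAsFactors = FALSE)
  if ("cell_type" %in% names(meta)) cells$label <- as.character(meta$cell_type)

  extras <- list()
  for (nm in c("polygons", "tx"))
    if (!is.na(paths[[nm]])) extras[[nm]] <- read_flat_csv(paths[[nm]])

  CosmxExperiment(counts, cells, off, extras = extras)
}

#' Write a CosmxExperiment as CosMx-style flat files
#'
#' Emits the same flat-file dialect that \code{\link{readCosmx}} parses,
#' so that \code{readCosmx(writeCosmx(x, d))} reproduces \code{x}.
#' Coordinates are written in the container's um units (i.e. a reader with
#' \code{coordinateScale = 1} round-trips). Output is deterministic:
#' identical objects produce byte-identical files.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param directory Output directory (created if absent).
#' @param gzip Write \code{.csv.gz} (default) or plain \code{.csv}.
#' @return The directory path, invisibly.
#' @export
writeCosmx <- function(x, directory, gzip = TRUE) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  cd <- SummarizedExperiment::colData(x)
  off <- fovOffsets(x)
  fov <- fovs(x)
  oi <- match(fov, as.character(off$fov))
  xl <- if ("x_local" %in% colnames(cd)) cd$x_local else cd$x - off$x_offset[oi]
  yl <- if ("y_local" %in% colnames(cd)) cd$y_local else cd$y - off$y_offset[oi]
  ## strip the composite prefix back to a per-FOV integer id where possible
  raw_id <- sub("^f[^_]*_c", "", colnames(x))

  ext <- if (gzip) ".csv.gz" else ".csv"
  wcsv <- function(df, stem) {
    p <- file.path(directory, paste0(stem, ext))
    con <- if (gzip) gzfile(p, "wt") else file(p, "wt")
    on.exit(close(con))
    ## full-precision doubles so coordinates round-trip exactly
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    p
  }

  cnt <- SummarizedExperiment::assay(x, "counts")
  expr <- data.frame(fov = fov, cell_ID = raw_id, check.names = FALSE)
  tdf <- as.data.frame(as.matrix(t(cnt)), check.names = FALSE)
  rownames(tdf) <- NULL
  expr <- cbind(expr, tdf)
  wcsv(expr, "exprMat_file")

  meta <- data.frame(fov = fov, cell_ID = raw_id,
                     CenterX_local_px = as.numeric(xl),
                     CenterY_local_px = as.numeric(yl))
  lab <- cellLabels(x)
  if (any(!is.na(lab))) meta$cell_type <- unname(lab)
  wcsv(meta, "metadata_file")

  wcsv(data.frame(fov = off$fov, x_global_px = as.numeric(off$x_offset),
                  y_global_px = as.numeric(off$y_offset)),
       "fov_positions_file")

  extras <- S4Vectors::metadata(x)$extras
  if (!is.null(extras$polygons)) wcsv(extras$polygons, "polygons")
  if (!is.null(extras$tx)) wcsv(extras$tx, "tx_file")
  invisible(directory)
}

#' Write / read a labelled matrix as CSV
#'
#' Plain comma-delimited serialization for the pipeline's tabular outputs
#' (enrichment matrices, summaries): header row of column labels, first
#' column of row labels, labels quoted so embedded commas survive. Doubles
#' are written at full precision (\code{\%.17g}) so
#' \code{readMatrixCSV(writeMatrixCSV(m, p))} reproduces \code{m} exactly
#' (integer input comes back as numeric).
#'
#' @param m Matrix with unique row and column labels.
#' @param path Output file path.
#' @return \code{writeMatrixCSV}: \code{path}, invisibly.
#' @export
writeMatrixCSV <- function(m, path) {
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    nk_error("bad_labels", "matrix must have unique row and column labels")
  df <- as.data.frame(m, check.names = FALSE)
  if (is.numeric(m))
    df[] <- lapply(df, function(v) sprintf("%.17g", as.double(v)))
  ok <- tryCatch({
    suppressWarnings(write.csv(df, path, row.names = TRUE, quote = TRUE))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    nk_error("io", paste0("cannot write ", path, ": ", conditionMessage(ok)))
  invisible(path)
}

#' @rdname writeMatrixCSV
#' @return \code{readMatrixCSV}: the matrix.
#' @export
readMatrixCSV <- function(path) {
  if (!file.exists(path))
    nk_error("missing_file", paste0("file not found: ", path))
  df <- read.csv(path, row.names = 1, check.names = FALSE,
                 stringsAsFactors = FALSE)
  as.matrix(df)
}

#' Write a count matrix as MatrixMarket triplet plus label files
#'
#' Optional sparse export of the raw count matrix: \code{counts.mtx} with
#' companion \code{genes.txt} and \code{cells.txt} (one label per line).
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param directory Output directory.
#' @return The directory, invisibly.
#' @export
writeCountsMTX <- function(x, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  m <- as(as(SummarizedExperiment::assay(x, "counts"), "CsparseMatrix"),
          "generalMatrix")
  Matrix::writeMM(m, file.path(directory, "counts.mtx"))
  writeLines(rownames(x), file.path(directory, "genes.txt"))
  writeLines(colnames(x), file.path(directory, "cells.txt"))
  invisible(directory)
}
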