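#' k-nearest neighbors within each field of view
#'
#' For every cell, finds its \code{min(k, n_fov - 1)} nearest cells by
#' Euclidean distance in global um coordinates, restricted to the cell's
#' own FOV (tiles are imaged independently; neighborhoods never cross
#' tile boundaries). The cell itself is excluded. Ties at the k-th
#' distance are broken by ascending cell id so results are deterministic.
#' A FOV containing a single cell yields an empty neighbor set with a
#' warning.
#'
#' Distances are computed from a per-FOV all-pairs distance matrix; at
#' CosMx tile scale (hundreds to a few thousand cells per FOV) this is
#' exact and fast without spatial indexing.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param k Number of neighbors (default 150).
#' @return An object of class \code{NeighborIndex}: list with
#'   \code{neighbors} (named list, cell id -> character vector of
#'   neighbor ids in increasing-distance order) and \code{fov} (named
#'   vector of FOV per cell).
#' @examples
#' ce <- generateSpatial(simConfig(seed = 1))$dataset
#' nb <- knnWithinFov(ce, k = 5)
#' lengths(nb$neighbors)[1:3]
#' @export
knnWithinFov <- function(x, k = 150) {
  stopifnot(k >= 1)
  ids <- colnames(x)
  fov <- fovs(x)
  xy <- spatialCoords(x)
  neighbors <- vector("list", length(ids))
  names(neighbors) <- ids
  for (f in unique(fov)) {
    sel <- which(fov == f)
    n <- length(sel)
    if (n == 1) {
      nk_warn("singleton_fov",
              paste0("FOV ", f, " has a single cell; empty neighbor set"))
      neighbors[[sel]] <- character(0)
      next
    }
    d <- as.matrix(stats::dist(xy[sel, , drop = FALSE]))
    sub_ids <- ids[sel]
    kk <- min(k, n - 1)
    for (i in seq_len(n)) {
      di <- d[i, -i]
      oi <- sub_ids[-i]
      ord <- order(di, oi)[seq_len(kk)]
      neighbors[[sel[i]]] <- oi[ord]
    }
  }
  structure(list(neighbors = neighbors, fov = setNames(fov, ids), k = k),
            class = "NeighborIndex")
}

#' Tabulate neighbor cell types per focal cell
#'
#' Counts, for each focal cell, how many of its k nearest within-FOV
#' neighbors carry each cell-type label. Stored sparsely (cells x
#' receiver types); per-FOV tables are implicitly aggregated since the
#' neighbor index never crosses FOVs.
#'
#' @param nb A \code{NeighborIndex} from \code{\link{knnWithinFov}}.
#' @param labels Named character vector, cell id -> label (NA =
#'   unlabelled).
#' @param unlabeled How to treat unlabelled neighbors: \code{"drop"}
#'   (default; dropped with one warning) or \code{"error"}.
#' @return A sparse \code{dgCMatrix}, rows = focal cell ids, columns =
#'   label vocabulary (sorted), entries = neighbor counts.
#' @export
tabulateNeighborTypes <- function(nb, labels,
                                  unlabeled = c("drop", "error")) {
  unlabeled <- match.arg(unlabeled)
  cells <- names(nb$neighbors)
  types <- sort(unique(labels[!is.na(labels)]))
  if (length(types) == 0)
    nk_error("no_labels", "no labelled cells")
  deg <- lengths(nb$neighbors)
  focal <- rep(seq_along(cells), deg)
  nbr <- unlist(nb$neighbors, use.names = FALSE)
  nbr_lab <- unname(labels[nbr])
  if (anyNA(nbr_lab)) {
    if (unlabeled == "error")
      nk_error("unlabeled_neighbor",
               paste0(sum(is.na(nbr_lab)), " neighbor(s) lack a label"))
    nk_warn("unlabeled_neighbor",
            paste0("dropping ", sum(is.na(nbr_lab)),
                   " unlabelled neighbor occurrence(s)"))
    keep <- !is.na(nbr_lab)
    focal <- focal[keep]; nbr_lab <- nbr_lab[keep]
  }
  prof <- Matrix::sparseMatrix(
    i = focal, j = match(nbr_lab, types), x = 1,
    dims = c(length(cells), length(types)),
    dimnames = list(cells, types))
  prof
}

#' Neighborhood-enrichment percentage matrix
#'
#' Aggregates per-cell neighbor-type counts into a sender x receiver
#' percentage matrix: (i) labels with fewer than \code{minCellsPerType}
#' total cells are excluded as both sender and receiver; (ii) neighbor
#' counts are summed within each sender group,
#' \code{raw[s, r] = sum over cells of type s of their type-r neighbor
#' counts}; (iii) each column is normalized by the total number of
#' potential neighbors of that receiver type, i.e. the number of type-r
#' cells in the analysed dataset; (iv) each row is rescaled to sum to
#' 100. Step (iii) corrects for receiver abundance (without it the matrix
#' is raw neighborhood composition); disable it with
#' \code{abundanceNormalize = FALSE}.
#'
#' @param profiles Sparse cells x types count matrix from
#'   \code{\link{tabulateNeighborTypes}}.
#' @param labels Named character vector, cell id -> label, covering the
#'   analysed dataset (used both for sender grouping and for receiver
#'   abundances).
#' @param minCellsPerType Exclusion threshold on total cells per label
#'   across all FOVs (default 20).
#' @param abundanceNormalize Apply step (iii) (default TRUE).
#' @return Numeric sender x receiver matrix whose non-zero rows each sum
#'   to 100; attributes \code{label_totals} and \code{excluded} record
#'   the abundances used and the labels dropped by the min-cell rule.
#' @examples
#' ce <- generateSpatial(simConfig(seed = 1))$dataset
#' nb <- knnWithinFov(ce, k = 10)
#' prof <- tabulateNeighborTypes(nb, cellLabels(ce))
#' em <- enrichmentMatrix(prof, cellLabels(ce))
#' rowSums(em)
#' @export
enrichmentMatrix <- function(profiles, labels, minCellsPerType = 20,
                             abundanceNormalize = TRUE) {
  lab <- labels[!is.na(labels)]
  totals <- table(lab)
  keep <- names(totals)[totals >= minCellsPerType]
  if (length(keep) == 0)
    nk_error("all_types_excluded",
             sprintf("no cell type reaches %d total cells", minCellsPerType))
  keep <- sort(keep)
  recv <- intersect(keep, colnames(profiles))
  raw <- matrix(0, nrow = length(keep), ncol = length(keep),
                dimnames = list(sender = keep, receiver = keep))
  for (s in keep) {
    cells_s <- intersect(names(lab)[lab == s], rownames(profiles))
    if (length(cells_s))
      raw[s, recv] <- Matrix::colSums(profiles[cells_s, recv, drop = FALSE])
  }
  norm <- raw
  if (abundanceNormalize) {
    n_r <- as.numeric(totals[keep])
    norm <- sweep(raw, 2, n_r, "/")
  }
  rs <- rowSums(norm)
  nz <- rs > 0
  norm[nz, ] <- 100 * norm[nz, , drop = FALSE] / rs[nz]
  attr(norm, "label_totals") <- setNames(as.numeric(totals[keep]), keep)
  attr(norm, "excluded") <- setdiff(names(totals), keep)
  attr(norm, "abundance_normalized") <- abundanceNormalize
  norm
}

#' One-call neighborhood enrichment
#'
#' Chains \code{\link{knnWithinFov}}, \code{\link{tabulateNeighborTypes}}
#' and \code{\link{enrichmentMatrix}} on a labelled dataset.
#'
#' @param x A labelled \linkS4class{CosmxExperiment}.
#' @param labels Named label vector (default \code{cellLabels(x)}).
#' @param k Neighbors per cell (default 150).
#' @param minCellsPerType Label exclusion threshold (default 20).
#' @param abundanceNormalize See \code{\link{enrichmentMatrix}}.
#' @return The enrichment matrix.
#' @export
neighborhoodEnrichment <- function(x, labels = cellLabels(x), k = 150,
                                   minCellsPerType = 20,
                                   abundanceNormalize = TRUE) {
  nb <- knnWithinFov(x, k = k)
  prof <- tabulateNeighborTypes(nb, labels)
  enrichmentMatrix(prof, labels, minCellsPerType = minCellsPerType,
                   abundanceNormalize = abundanceNormalize)
}

#' Label-permutation null for one enrichment entry
#'
#' Empirical significance of the observed \code{[sender, receiver]}
#' enrichment against a null in which cell-type labels are permuted
#' across cells (positions and neighbor graph fixed, composition
#' preserved). The p-value uses the standard add-one estimator
#' \code{(1 + #(null >= observed)) / (1 + nPerm)}.
#'
#' @param nb A \code{NeighborIndex}.
#' @param labels Named label vector.
#' @param sender,receiver Labels indexing the tested entry.
#' @param nPerm Number of permutations (default 99).
#' @param minCellsPerType,abundanceNormalize Passed to
#'   \code{\link{enrichmentMatrix}}.
#' @param seed Optional RNG seed for the permutations.
#' @return List with \code{observed}, \code{null} (vector of permuted
#'   values) and \code{p_value}.
#' @export
enrichmentPermutationTest <- function(nb, labels, sender, receiver,
                                      nPerm = 99, minCellsPerType = 20,
                                      abundanceNormalize = TRUE,
                                      seed = NULL) {
  run1 <- function(lv) {
    prof <- suppressWarnings(tabulateNeighborTypes(nb, lv))
    em <- enrichmentMatrix(prof, lv, minCellsPerType = minCellsPerType,
                           abundanceNormalize = abundanceNormalize)
    if (!sender %in% rownames(em) || !receiver %in% colnames(em))
      return(NA_real_)
    em[sender, receiver]
  }
  obs <- run1(labels)
  if (is.na(obs))
    nk_error("unknown_label",
             "sender or receiver excluded from the enrichment matrix")
  doperm <- function() {
    vapply(seq_len(nPerm), function(i) {
      perm <- labels
      idx <- which(!is.na(labels))
      perm[idx] <- labels[idx][sample.int(length(idx))]
      run1(perm)
    }, numeric(1))
  }
  null <- if (is.null(seed)) doperm() else with_seed(seed, doperm())
  p <- (1 + sum(null >= obs, na.rm = TRUE)) / (1 + nPerm)
  list(observed = obs, null = null, p_value = p)
}
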