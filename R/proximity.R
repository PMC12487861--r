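#' Distance from each query cell to its nearest target cell
#'
#' For each query cell, the minimum Euclidean distance (um) to any target
#' cell in scope. Scope \code{"within_fov"} (default) restricts targets
#' to the query's own FOV — distances stitched across non-adjacent tiles
#' are physically meaningless — while \code{"global"} uses all targets. A
#' query cell that is itself a target reports its distance to the nearest
#' \emph{other} target. Queries with no in-scope target get \code{NA}
#' with a warning and are excluded downstream.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param queryIds,targetIds Character vectors of cell ids.
#' @param scope \code{"within_fov"} or \code{"global"}.
#' @return data.frame with columns \code{cell_id}, \code{fov},
#'   \code{distance_um}.
#' @examples
#' cells <- data.frame(id = c("q", "t1", "t2"), fov = 1,
#'                     x = c(0, 3, 10), y = c(0, 4, 0))
#' cnt <- matrix(0L, 1, 3, dimnames = list("IL36G", NULL))
#' ce <- CosmxExperiment(cnt, cells, data.frame(fov = 1, x_offset = 0, y_offset = 0))
#' nearestTargetDistance(ce, "q", c("t1", "t2"))$distance_um # 5
#' @export
nearestTargetDistance <- function(x, queryIds, targetIds,
                                  scope = c("within_fov", "global")) {
  scope <- match.arg(scope)
  if (length(targetIds) == 0)
    nk_error("no_targets", "target set is empty")
  ids <- colnames(x)
  bad <- setdiff(c(queryIds, targetIds), ids)
  if (length(bad))
    nk_error("unknown_cell",
             paste0("unknown cell id(s): ", paste(bad, collapse = ", ")))
  xy <- spatialCoords(x)
  fov <- setNames(fovs(x), ids)
  out <- data.frame(cell_id = queryIds, fov = unname(fov[queryIds]),
                    distance_um = NA_real_, stringsAsFactors = FALSE)
  groups <- if (scope == "within_fov") split(seq_along(queryIds),
                                             out$fov) else
    list(all = seq_along(queryIds))
  for (g in names(groups)) {
    qi <- groups[[g]]
    tg <- if (scope == "within_fov")
      targetIds[fov[targetIds] == g] else targetIds
    if (length(tg) == 0) next
    qxy <- xy[queryIds[qi], , drop = FALSE]
    txy <- xy[tg, , drop = FALSE]
    ## squared cross-distances via outer sums; exact at these scales
    d2 <- outer(rowSums(qxy^2), rowSums(txy^2), "+") - 2 * qxy %*% t(txy)
    d2[d2 < 0] <- 0
    ## self-target: a query appearing in the target set must not match itself
    self <- match(queryIds[qi], tg)
    has_self <- !is.na(self)
    d2[cbind(which(has_self), self[has_self])] <- Inf
    dmin <- sqrt(apply(d2, 1, min))
    dmin[!is.finite(dmin)] <- NA_real_  # lone self-target in scope
    out$distance_um[qi] <- dmin
  }
  if (anyNA(out$distance_um))
    nk_warn("no_target_in_scope",
            paste0(sum(is.na(out$distance_um)),
                   " query cell(s) have no in-scope target; distance NA"))
  out
}

#' Stratify nearest-target distances into Near and Far
#'
#' Adds a \code{stratum} column: \code{"Near"} iff the distance is
#' strictly below the threshold, \code{"Far"} at or above it (a cell at
#' exactly the threshold is Far). NA distances get NA stratum.
#'
#' @param table data.frame with a \code{distance_um} column.
#' @param nearThreshold Threshold in um (default 20).
#' @return The table with a \code{stratum} column appended.
#' @export
stratifyProximity <- function(table, nearThreshold = 20) {
  stopifnot(nearThreshold > 0)
  table$stratum <- ifelse(is.na(table$distance_um), NA_character_,
                          ifelse(table$distance_um < nearThreshold,
                                 "Near", "Far"))
  attr(table, "near_threshold") <- nearThreshold
  table
}

#' Proximity of gated immune subsets to a target population
#'
#' Convenience wrapper assembling the full proximity table: for every
#' cell of each query subset, the distance to the nearest target cell
#' (\code{\link{nearestTargetDistance}}) and its Near/Far stratum
#' (\code{\link{stratifyProximity}}). Subsets may overlap (gates are
#' independent); a multi-gated cell contributes one row per subset. Cells
#' gated into both a query subset and the target population stay as
#' queries but are excluded from their own target set.
#'
#' @param x A \linkS4class{CosmxExperiment}.
#' @param gating Either a \code{GatingResult} from \code{\link{gateCells}}
#'   or a named label vector (cell id -> label).
#' @param subsets Query subset labels (default the four immune gates).
#' @param target Target subset label (default \code{"IL36G_KC"}).
#' @param nearThreshold Near/Far cut in um (default 20).
#' @param scope Distance scope, see \code{\link{nearestTargetDistance}}.
#' @return data.frame with columns \code{cell_id}, \code{subset},
#'   \code{fov}, \code{distance_um}, \code{stratum}; NA-distance rows are
#'   dropped (with the warning raised by the distance step).
#' @export
proximityAnalysis <- function(x, gating,
                              subsets = c("Treg", "Th17", "regTh17", "NKT"),
                              target = "IL36G_KC", nearThreshold = 20,
                              scope = c("within_fov", "global")) {
  scope <- match.arg(scope)
  member <- function(lbl) {
    if (inherits(gating, "GatingResult")) gatedCells(gating, lbl)
    else names(gating)[!is.na(gating) & gating == lbl]
  }
  target_ids <- member(target)
  if (length(target_ids) == 0)
    nk_error("no_targets", paste0("no cells carry target label '", target, "'"))
  rows <- lapply(subsets, function(s) {
    q <- member(s)
    if (length(q) == 0) return(NULL)
    tab <- nearestTargetDistance(x, q, target_ids, scope = scope)
    tab$subset <- s
    tab
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    nk_error("no_queries", "no cells carry any query subset label")
  tab <- tab[!is.na(tab$distance_um), , drop = FALSE]
  tab <- stratifyProximity(tab, nearThreshold)
  tab[, c("cell_id", "subset", "fov", "distance_um", "stratum")]
}

#' Near/Far proportions per subset
#'
#' @param table A stratified proximity table (columns \code{subset},
#'   \code{stratum}).
#' @return data.frame with one row per subset: \code{subset},
#'   \code{prop_near}, \code{prop_far}, \code{n}; proportions sum to 1.
#'   Subsets with no rows are omitted with a warning.
#' @export
subsetProportions <- function(table) {
  stopifnot(all(c("subset", "stratum") %in% names(table)))
  subs <- unique(table$subset)
  res <- do.call(rbind, lapply(subs, function(s) {
    st <- table$stratum[table$subset == s]
    n <- length(st)
    data.frame(subset = s, prop_near = sum(st == "Near") / n,
               prop_far = sum(st == "Far") / n, n = n)
  }))
  res
}

## Exact two-sided rank-sum p by enumeration over all C(n, n1) rank
## assignments (midranks, so ties are handled). Used for small samples.
ranksum_exact_enum <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  wobs <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(ws - e) >= abs(wobs - e) - 1e-12)
}

#' Wilcoxon rank-sum comparison of two distance samples
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. For small samples (both
#' groups <= 20) the exact null distribution is used: the standard exact
#' computation when there are no ties, otherwise full enumeration over
#' rank assignments (feasible at these sizes). Larger samples use the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param a,b Numeric vectors (e.g. nearest-target distances of two
#'   subsets). Both must be non-empty.
#' @return List with \code{statistic} (Mann-Whitney U of the first
#'   sample), \code{p_value} and \code{method}.
#' @examples
#' rankSumTest(c(1, 2), c(10, 11))$p_value # exact: 1/3
#' @export
rankSumTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    nk_error("empty_group", "both samples need at least one finite value")
  small <- length(a) <= 20 && length(b) <= 20
  ties <- anyDuplicated(c(a, b)) > 0
  u <- unname(stats::wilcox.test(a, b, exact = FALSE)$statistic)
  if (small && !ties) {
    p <- stats::wilcox.test(a, b, exact = TRUE,
                            alternative = "two.sided")$p.value
    method <- "exact"
  } else if (small && choose(length(a) + length(b), length(a)) <= 1e5) {
    p <- ranksum_exact_enum(a, b)
    method <- "exact enumeration (ties)"
  } else {
    p <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE,
                            alternative = "two.sided")$p.value
    method <- "normal approximation, tie-corrected"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Compare two subsets' nearest-target distances
#'
#' @param table A proximity table (columns \code{subset},
#'   \code{distance_um}).
#' @param subsetA,subsetB Subset labels to compare.
#' @return \code{\link{rankSumTest}} result.
#' @export
compareSubsets <- function(table, subsetA, subsetB) {
  da <- table$distance_um[table$subset == subsetA]
  db <- table$distance_um[table$subset == subsetB]
  if (length(da) == 0 || length(db) == 0)
    nk_error("empty_group",
             paste0("subset with no distances: ",
                    if (length(da) == 0) subsetA else subsetB))
  rankSumTest(da, db)
}

#' All pairwise subset comparisons
#'
#' Runs \code{\link{compareSubsets}} on every pair of subsets present and,
#' as a sensitivity output, a Fisher exact test on the 2x2 Near/Far count
#' table of each pair. No multiplicity correction is applied by default;
#' \code{adjust = "BH"} adds Benjamini-Hochberg adjusted p-values.
#'
#' @param table A stratified proximity table.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return data.frame: \code{subset_a}, \code{subset_b},
#'   \code{statistic}, \code{p_value}, \code{p_near_far} (Fisher 2x2),
#'   and \code{p_adj} if requested.
#' @export
comparePairwise <- function(table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  subs <- sort(unique(table$subset))
  if (length(subs) < 2)
    nk_error("empty_group", "need at least two subsets to compare")
  pairs <- utils::combn(subs, 2)
  res <- do.call(rbind, apply(pairs, 2, function(p) {
    ct <- compareSubsets(table, p[1], p[2])
    m <- vapply(p, function(s) {
      st <- table$stratum[table$subset == s]
      c(sum(st == "Near"), sum(st == "Far"))
    }, numeric(2))
    pf <- if (all(colSums(m) > 0)) stats::fisher.test(m)$p.value else NA_real_
    data.frame(subset_a = p[1], subset_b = p[2], statistic = ct$statistic,
               p_value = ct$p_value, p_near_far = pf)
  }))
  if (adjust == "BH") res$p_adj <- stats::p.adjust(res$p_value, "BH")
  res
}
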