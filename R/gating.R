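#' Marker-based gating rules
#'
#' A gating rule names a cell subset and the markers whose coexpression
#' defines it: a cell carries the label iff its raw count is at least
#' \code{minCount} for \emph{every} required marker. Rules are independent
#' gates, not a partition — a cell may satisfy several rules at once.
#'
#' @param name Subset label.
#' @param markers Character vector of required marker genes (non-empty,
#'   unique after normalization).
#' @param minCount Positivity threshold on the raw transcript count
#'   (default 1, i.e. any detected expression).
#' @return A list of class \code{GatingRule}.
#' @examples
#' gatingRule("regTh17", c("IL17F", "IL26", "FOXP3"))
#' @export
gatingRule <- function(name, markers, minCount = 1) {
  markers <- as.character(markers)
  if (length(markers) == 0)
    nk_error("bad_rule", "a gating rule needs at least one marker")
  if (anyDuplicated(normalizeMarkerNames(markers)))
    nk_error("bad_rule", paste0("duplicate markers in rule '", name, "'"))
  if (minCount < 1)
    nk_error("bad_rule", "positivity threshold must be >= 1")
  structure(list(name = as.character(name), markers = markers,
                 minCount = minCount), class = "GatingRule")
}

#' @export
print.GatingRule <- function(x, ...) {
  cat(sprintf("GatingRule %s: %s (count >= %d)\n", x$name,
              paste(x$markers, collapse = "+"), x$minCount))
  invisible(x)
}

#' Built-in immune and keratinocyte gating rules
#'
#' The five marker-defined populations used throughout the proximity
#' analysis: IL-36G+ keratinocytes (IL36G), Treg (CD4+FOXP3+IL2RA+),
#' Th17 (CD4+IL17A+RORC+), regTh17 (IL17F+IL26+FOXP3+) and NKT
#' (CD8A+NKG7+KLRD1+).
#'
#' @param minCount Positivity threshold applied to every rule (default 1).
#' @return Named list of \code{\link{gatingRule}} objects.
#' @examples
#' names(builtinRules())
#' @export
builtinRules <- function(minCount = 1) {
  defs <- list(
    IL36G_KC = "IL36G",
    Treg     = c("CD4", "FOXP3", "IL2RA"),
    Th17     = c("CD4", "IL17A", "RORC"),
    regTh17  = c("IL17F", "IL26", "FOXP3"),
    NKT      = c("CD8A", "NKG7", "KLRD1"))
  lapply(setNames(names(defs), names(defs)),
         function(n) gatingRule(n, defs[[n]], minCount))
}

#' Gate cells into marker-defined subsets
#'
#' Applies each rule as an AND over its markers on the raw count matrix:
#' a cell is assigned the rule's label iff every required marker has raw
#' count >= the rule's positivity threshold. Marker names are matched
#' after normalization (case-folded, hyphens stripped), so \code{IL-17F}
#' in a rule matches a panel feature \code{IL17F}.
#'
#' @param x A \linkS4class{CosmxExperiment} (or a raw genes x cells count
#'   matrix with gene rownames and cell-id colnames).
#' @param rules List of \code{\link{gatingRule}} objects (default
#'   \code{\link{builtinRules}()}).
#' @return A list of class \code{GatingResult} with \code{assignments} (a
#'   cells x rules logical matrix), \code{counts} (cells per label) and
#'   \code{rules}.
#' @examples
#' cnt <- matrix(c(2L, 1L, 1L), nrow = 3,
#'               dimnames = list(c("IL17F", "IL26", "FOXP3"), "c1"))
#' gateCells(cnt, builtinRules()["regTh17"])$counts
#' @export
gateCells <- function(x, rules = builtinRules()) {
  counts <- if (is(x, "CosmxExperiment"))
    SummarizedExperiment::assay(x, "counts") else x
  genes <- rownames(counts)
  all_markers <- unique(unlist(lapply(rules, `[[`, "markers")))
  hit <- match_markers(all_markers, genes)
  if (anyNA(hit))
    nk_error("missing_marker",
             paste0("marker gene(s) absent from dataset: ",
                    paste(all_markers[is.na(hit)], collapse = ", ")),
             markers = all_markers[is.na(hit)])
  n <- ncol(counts)
  labs <- unname(vapply(rules, `[[`, character(1), "name"))
  assign <- matrix(FALSE, nrow = n, ncol = length(rules),
                   dimnames = list(colnames(counts), labs))
  if (n > 0) {
    for (j in seq_along(rules)) {
      r <- rules[[j]]
      idx <- match_markers(r$markers, genes)
      sub <- counts[idx, , drop = FALSE] >= r$minCount
      assign[, j] <- if (is(sub, "Matrix")) Matrix::colSums(sub) == length(idx)
                     else colSums(sub) == length(idx)
    }
  }
  structure(list(assignments = assign,
                 counts = colSums(assign),
                 rules = rules), class = "GatingResult")
}

#' @export
print.GatingResult <- function(x, ...) {
  cat(sprintf("GatingResult: %d cells x %d rules\n",
              nrow(x$assignments), ncol(x$assignments)))
  print(x$counts)
  invisible(x)
}

#' Cell ids carrying a given gated label
#'
#' @param result A \code{GatingResult}.
#' @param label Subset label.
#' @return Character vector of cell ids.
#' @export
gatedCells <- function(result, label) {
  if (!label %in% colnames(result$assignments))
    nk_error("unknown_label", paste0("no gating rule named '", label, "'"))
  rownames(result$assignments)[result$assignments[, label]]
}

#' Read gating rules from a plain-text config
#'
#' One rule per line: the subset label, then its comma-separated markers,
#' optionally ending in a bare integer positivity threshold. Blank lines
#' and lines starting with \code{#} are ignored.
#'
#' \preformatted{regTh17, IL17F, IL26, FOXP3
#' IL36G_KC, IL36G, 2}
#'
#' @param path Path to the rules file.
#' @return Named list of \code{\link{gatingRule}} objects.
#' @export
readGatingRules <- function(path) {
  if (!file.exists(path))
    nk_error("missing_file", paste0("file not found: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rules <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, ",")[[1]])
    if (length(parts) < 2)
      nk_error("bad_rule", paste0("cannot parse rule line: ", ln))
    minc <- 1
    if (grepl("^[0-9]+$", parts[length(parts)])) {
      minc <- as.integer(parts[length(parts)])
      parts <- parts[-length(parts)]
    }
    gatingRule(parts[1], parts[-1], minc)
  })
  setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

#' Write gating assignments as a long-format CSV
#'
#' Emits one \code{(cell_id, label)} row per assignment.
#'
#' @param result A \code{GatingResult}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeGating <- function(result, path) {
  idx <- which(result$assignments, arr.ind = TRUE)
  df <- data.frame(
    cell_id = rownames(result$assignments)[idx[, 1]],
    label = colnames(result$assignments)[idx[, 2]])
  df <- df[order(df$cell_id, df$label), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
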