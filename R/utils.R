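## Internal helpers shared across modules.

#' @importFrom methods is new validObject as
#' @importFrom stats median rnbinom runif setNames
#' @importFrom utils read.csv write.csv packageVersion
NULL

## Structured condition constructor: every user-facing failure carries a
## machine-readable class ("nichekit_error_<what>") plus free data fields.
nk_error <- function(what, message, ...) {
  stop(structure(
    class = c(paste0("nichekit_error_", what), "nichekit_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

nk_warn <- function(what, message, ...) {
  warning(structure(
    class = c(paste0("nichekit_warning_", what), "nichekit_warning",
              "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Normalize gene/marker names for matching
#'
#' Panel annotations and free text spell markers differently (IL-17F vs
#' IL17F, Foxp3 vs FOXP3). Matching is done on an upper-cased,
#' hyphen/underscore-stripped form.
#'
#' @param x Character vector of gene or marker names.
#' @return Character vector of normalized names.
#' @examples
#' normalizeMarkerNames(c("IL-17F", "Foxp3")) # "IL17F" "FOXP3"
#' @export
normalizeMarkerNames <- function(x) {
  toupper(gsub("[-_]", "", as.character(x)))
}

## Match `markers` against `genes` after normalization; returns integer
## indices into `genes`, NA where absent.
match_markers <- function(markers, genes) {
  match(normalizeMarkerNames(markers), normalizeMarkerNames(genes))
}

is_count_like <- function(m) {
  if (is(m, "sparseMatrix")) x <- m@x else x <- as.vector(m)
  x <- x[!is.na(x)]
  all(x >= 0) && all(x == trunc(x))
}

## Column sums that work for both dense and Matrix classes.
col_totals <- function(m) {
  if (is(m, "Matrix")) Matrix::colSums(m) else colSums(m)
}
row_totals <- function(m) {
  if (is(m, "Matrix")) Matrix::rowSums(m) else rowSums(m)
}
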