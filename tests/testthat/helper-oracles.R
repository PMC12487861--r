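## Shared fixtures and independent reference implementations used to
## cross-check the package's vectorised code paths.

## Minimal CosmxExperiment from coordinate/label vectors (zero counts
## unless given); one gene so validity holds.
make_ce <- function(x, y, fov = rep("1", length(x)),
                    label = NULL, ids = NULL, counts = NULL,
                    offsets = NULL) {
  n <- length(x)
  if (is.null(ids)) ids <- sprintf("c%03d", seq_len(n))
  cells <- data.frame(id = ids, fov = as.character(fov), x = x, y = y,
                      stringsAsFactors = FALSE)
  if (!is.null(label)) cells$label <- label
  if (is.null(counts))
    counts <- matrix(0L, 1, n, dimnames = list("G1", NULL))
  if (is.null(offsets))
    offsets <- data.frame(fov = unique(as.character(fov)),
                          x_offset = 0, y_offset = 0)
  CosmxExperiment(counts, cells, offsets)
}

## Brute-force k-NN: per-cell loop over all same-FOV cells, explicit
## distances, sort by (distance, id).
bf_knn <- function(ce, k) {
  xy <- spatialCoords(ce); fov <- fovs(ce); ids <- colnames(ce)
  out <- list()
  for (i in seq_along(ids)) {
    same <- setdiff(which(fov == fov[i]), i)
    d <- sqrt((xy[same, 1] - xy[i, 1])^2 + (xy[same, 2] - xy[i, 2])^2)
    ord <- order(d, ids[same])
    out[[ids[i]]] <- ids[same][ord][seq_len(min(k, length(same)))]
  }
  out
}

## Brute-force neighborhood enrichment: hand loops over the published
## procedure — exclusion, per-sender summation, receiver-abundance
## normalisation, row rescale to 100.
bf_enrichment <- function(ce, labels, k, min_cells) {
  nbrs <- bf_knn(ce, k)
  lab <- labels[!is.na(labels)]
  totals <- table(lab)
  keep <- sort(names(totals)[totals >= min_cells])
  stopifnot(length(keep) > 0)
  raw <- matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (s in keep) {
    for (cid in names(lab)[lab == s]) {
      nl <- labels[nbrs[[cid]]]
      for (r in keep) raw[s, r] <- raw[s, r] + sum(nl == r, na.rm = TRUE)
    }
  }
  norm <- sweep(raw, 2, as.numeric(totals[keep]), "/")
  rs <- rowSums(norm); nz <- rs > 0
  norm[nz, ] <- 100 * norm[nz, , drop = FALSE] / rs[nz]
  norm
}

## Random labelled dataset for oracle-equivalence checks.
random_ce <- function(n, n_types = 3, n_fovs = 2) {
  fov <- as.character(sample.int(n_fovs, n, replace = TRUE))
  ## guarantee every FOV has at least 2 cells
  for (f in as.character(seq_len(n_fovs)))
    if (sum(fov == f) < 2) fov[sample.int(n, 2)] <- f
  make_ce(x = runif(n, 0, 300), y = runif(n, 0, 300), fov = fov,
          label = sample(LETTERS[seq_len(n_types)], n, replace = TRUE),
          offsets = data.frame(fov = as.character(seq_len(n_fovs)),
                               x_offset = (seq_len(n_fovs) - 1) * 400,
                               y_offset = 0))
}

## Planted-niche study conditions used by the recovery checks.
planted_config <- function(seed, nFovs = 2) {
  simConfig(seed = seed, nFovs = nFovs,
            niches = list(list(subset = "regTh17", anchor = "IL36G_KC",
                               radius = 15, fraction = 0.8)))
}
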