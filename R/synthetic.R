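#' Simulation configuration for synthetic spatial datasets
#'
#' Describes a multi-FOV spatial dataset with marker-driven cell types
#' and optional planted co-localisation niches. Defaults emulate a small
#' CosMx-like tissue tile-set: two 500 x 500 um FOVs; six cell types
#' (IL-36G+ keratinocyte anchors, the four gated immune subsets, and an
#' ungated "Other" background population); negative-binomial transcript
#' counts over the builtin marker panel plus housekeeping genes and
#' negative/system control probes; and one niche in which 80\% of
#' regTh17-like cells are placed within 15 um of a random IL36G_KC
#' anchor.
#'
#' Under the default count model a planted subset cell carries all three
#' of its gate markers with probability about 0.98 (marker mean 12,
#' dispersion 3), and off-subset cells pass a foreign gate with
#' probability well under 0.05, so planted labels and
#' \code{\link{gateCells}} output agree on >= 95\% of cells.
#'
#' @param seed Integer RNG seed; identical configs generate identical
#'   datasets.
#' @param nFovs Number of fields of view (default 2).
#' @param fovSize FOV width and height in um (default \code{c(500, 500)}).
#' @param abundances Named vector of exact per-FOV cell counts per type.
#' @param niches List of niche specs, each
#'   \code{list(subset=, anchor=, radius=, fraction=)}: the given
#'   fraction of \code{subset} cells is placed uniformly within
#'   \code{radius} um of a random \code{anchor} cell of the same FOV.
#' @param markerMean NB mean for a type's own gate markers (default 12).
#' @param backgroundMean NB mean for off-type markers (default 0.01).
#' @param dispersion NB size parameter (default 3).
#' @param nNegProbes,nSystemProbes Number of "Neg"/"System" control
#'   probes on the panel (defaults 6 and 2).
#' @param controlProbeMean NB mean for control probes (default 0.05).
#' @param minSpacing Declared minimum plausible cell spacing in um used
#'   only to reject configs denser than a tissue can be (default 2).
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1, nFovs = 2, fovSize = c(500, 500),
                      abundances = c(IL36G_KC = 60, Treg = 40, Th17 = 40,
                                     regTh17 = 40, NKT = 40, Other = 80),
                      niches = list(list(subset = "regTh17",
                                         anchor = "IL36G_KC",
                                         radius = 15, fraction = 0.8)),
                      markerMean = 12, backgroundMean = 0.01,
                      dispersion = 3, nNegProbes = 6, nSystemProbes = 2,
                      controlProbeMean = 0.05, minSpacing = 2) {
  stopifnot(length(fovSize) == 2, all(fovSize > 0), nFovs >= 1,
            all(abundances >= 0), !is.null(names(abundances)),
            dispersion > 0, markerMean > 0)
  for (ni in niches) {
    stopifnot(all(c("subset", "anchor", "radius", "fraction") %in% names(ni)),
              ni$radius > 0, ni$fraction >= 0, ni$fraction <= 1)
    if (!ni$subset %in% names(abundances) || !ni$anchor %in% names(abundances))
      nk_error("bad_config",
               paste0("niche refers to unknown type: ", ni$subset, "/", ni$anchor))
    if (ni$fraction > 0 && abundances[[ni$anchor]] == 0)
      nk_error("bad_config",
               paste0("niche anchor type '", ni$anchor, "' has zero abundance"))
  }
  n_per_fov <- sum(abundances)
  if (n_per_fov * 4 * minSpacing^2 > prod(fovSize))
    nk_error("too_dense", sprintf(
      "%d cells per FOV exceed capacity of a %g x %g um FOV at %g um spacing",
      n_per_fov, fovSize[1], fovSize[2], minSpacing))
  structure(list(seed = as.integer(seed), nFovs = nFovs, fovSize = fovSize,
                 abundances = abundances, niches = niches,
                 markerMean = markerMean, backgroundMean = backgroundMean,
                 dispersion = dispersion, nNegProbes = nNegProbes,
                 nSystemProbes = nSystemProbes,
                 controlProbeMean = controlProbeMean,
                 minSpacing = minSpacing), class = "SimConfig")
}

## Per-type NB mean matrix over the default synthetic panel.
sim_count_model <- function(config) {
  rules <- builtinRules()
  markers <- unique(unlist(lapply(rules, `[[`, "markers")))
  extra <- c("CD3E", "CTLA4")
  house <- c("KRT5", "KRT14", "ACTB", "B2M", "GAPDH", "COL1A1")
  ctrl <- c(if (config$nNegProbes > 0) paste0("NegPrb", seq_len(config$nNegProbes)),
            if (config$nSystemProbes > 0)
              paste0("SystemControl", seq_len(config$nSystemProbes)))
  genes <- c(markers, extra, house, ctrl)
  types <- names(config$abundances)
  mu <- matrix(config$backgroundMean, nrow = length(types),
               ncol = length(genes), dimnames = list(types, genes))
  mu[, house] <- 3
  mu[, ctrl] <- config$controlProbeMean
  for (ty in intersect(types, names(rules)))
    mu[ty, rules[[ty]]$markers] <- config$markerMean
  tcells <- intersect(types, c("Treg", "Th17", "regTh17", "NKT"))
  if (length(tcells)) mu[tcells, "CD3E"] <- 5
  reg <- intersect(types, c("Treg", "regTh17"))
  if (length(reg)) mu[reg, "CTLA4"] <- 4
  if ("regTh17" %in% types) mu["regTh17", "CD4"] <- 5
  if ("IL36G_KC" %in% types) mu["IL36G_KC", c("KRT5", "KRT14")] <- 6
  mu
}

#' Generate a synthetic multi-FOV spatial dataset with planted niches
#'
#' Places cells FOV by FOV: every type is laid down by a homogeneous
#' (uniform) point process, except that for each niche spec the
#' configured fraction of the attracted subset is placed uniformly
#' within the attraction radius of a randomly chosen anchor cell of the
#' same FOV (clipped to the FOV, which can only shorten the
#' anchor-to-cell distance). Transcript counts are drawn per cell from a
#' per-type negative-binomial model over the builtin marker panel,
#' housekeeping genes, and Neg/System control probes, so QC, gating,
#' enrichment and proximity can all be exercised end to end.
#'
#' Output is deterministic: the same \code{\link{simConfig}} (including
#' seed) yields an identical dataset, and flat files written from it are
#' byte-identical.
#'
#' @param config A \code{\link{simConfig}}.
#' @return List with \code{dataset} (a labelled
#'   \linkS4class{CosmxExperiment}), and \code{truth}: data.frame
#'   \code{cell_id}, \code{fov}, \code{label}, \code{in_niche} (was this
#'   cell placed by a niche attraction), \code{anchor_id} (the anchor it
#'   was attracted to, NA otherwise).
#' @examples
#' gs <- generateSpatial(simConfig(seed = 7))
#' gs$dataset
#' table(gs$truth$label, gs$truth$in_niche)
#' @export
generateSpatial <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    W <- config$fovSize[1]; H <- config$fovSize[2]
    mu <- sim_count_model(config)
    genes <- colnames(mu)
    types <- names(config$abundances)
    att_frac <- setNames(numeric(length(types)), types)
    att_anchor <- setNames(rep(NA_character_, length(types)), types)
    att_radius <- setNames(numeric(length(types)), types)
    for (ni in config$niches) {
      att_frac[ni$subset] <- ni$fraction
      att_anchor[ni$subset] <- ni$anchor
      att_radius[ni$subset] <- ni$radius
    }
    cells <- list(); truth <- list(); cnts <- list()
    for (f in seq_len(config$nFovs)) {
      ## anchors and non-attracted types first, then attracted subsets
      ord <- order(att_frac[types] > 0)
      fx <- numeric(0); fy <- numeric(0); flab <- character(0)
      fin <- logical(0); fanch <- integer(0)
      for (ty in types[ord]) {
        n <- config$abundances[[ty]]
        if (n == 0) next
        n_att <- round(att_frac[[ty]] * n)
        n_uni <- n - n_att
        ux <- runif(n_uni, 0, W); uy <- runif(n_uni, 0, H)
        ax <- numeric(0); ay <- numeric(0); aid <- character(0)
        if (n_att > 0) {
          anchors <- which(flab == att_anchor[[ty]])
          if (length(anchors) == 0)
            nk_error("bad_config",
                     paste0("no anchor cells of type ", att_anchor[[ty]],
                            " in FOV ", f))
          pick <- anchors[sample.int(length(anchors), n_att, replace = TRUE)]
          r <- att_radius[[ty]] * sqrt(runif(n_att))
          th <- runif(n_att, 0, 2 * pi)
          ax <- pmin(pmax(fx[pick] + r * cos(th), 0), W)
          ay <- pmin(pmax(fy[pick] + r * sin(th), 0), H)
        }
        new_in <- c(rep(FALSE, n_uni), rep(TRUE, n_att))
        new_anch <- c(rep(NA_integer_, n_uni),
                      if (n_att > 0) pick else integer(0))
        fx <- c(fx, ux, ax); fy <- c(fy, uy, ay)
        flab <- c(flab, rep(ty, n))
        fin <- c(fin, new_in)
        fanch <- c(fanch, new_anch)
      }
      ids <- .cell_id(f, seq_along(fx))
      anchor_ids <- ifelse(is.na(fanch), NA_character_, ids[fanch])
      cells[[f]] <- data.frame(
        id = ids, fov = as.character(f),
        x_local = fx, y_local = fy, label = flab,
        stringsAsFactors = FALSE)
      truth[[f]] <- data.frame(
        cell_id = ids, fov = as.character(f), label = flab,
        in_niche = fin, anchor_id = anchor_ids, stringsAsFactors = FALSE)
      ## counts: one NB draw per gene per cell, in cell order
      m <- matrix(0L, nrow = length(genes), ncol = length(fx),
                  dimnames = list(genes, ids))
      for (j in seq_along(fx))
        m[, j] <- rnbinom(length(genes), mu = mu[flab[j], ],
                          size = config$dispersion)
      storage.mode(m) <- "integer"
      cnts[[f]] <- m
    }
    cells <- do.call(rbind, cells)
    truth <- do.call(rbind, truth)
    counts <- do.call(cbind, cnts)
    off <- data.frame(fov = as.character(seq_len(config$nFovs)),
                      x_offset = (seq_len(config$nFovs) - 1) * (W * 1.2),
                      y_offset = 0)
    oi <- match(cells$fov, off$fov)
    cells$x <- off$x_offset[oi] + cells$x_local
    cells$y <- off$y_offset[oi] + cells$y_local
    ds <- CosmxExperiment(counts, cells, off)
    list(dataset = ds, truth = truth)
  })
}

#' Generate a toy scRNA-seq count matrix with planted QC violations
#'
#' Builds a genes x cells matrix of negative-binomial counts with a
#' designated block of mitochondrial genes (names prefixed \code{MT-}),
#' plus optional cells constructed to violate exactly one QC rule each,
#' and optional boundary cells sitting exactly on every threshold
#' (exactly 500 transcripts, 100 detected genes, 10\% mitochondrial) —
#' which the strict-inequality filter must retain. Background cells are
#' parameterised far from every threshold so only the planted cells are
#' ever removed.
#'
#' @param nCells Total cells including planted ones.
#' @param nGenes Total genes (default 300; at least 200).
#' @param nMitoGenes Mitochondrial genes among them (default 30).
#' @param seed RNG seed.
#' @param mitoFraction Target mitochondrial fraction of background cells
#'   (default 0.03; 0 silences the mito genes entirely).
#' @param plantLowTranscripts,plantLowGenes,plantHighMito Number of cells
#'   planted to violate, respectively, the transcript-total, detected-
#'   gene, and mitochondrial-fraction rule (each violating only that
#'   rule).
#' @param plantBoundary Number of exact-threshold cells (retained).
#' @return Integer matrix with \code{attr(, "planted")}: a list of cell
#'   ids per planted category.
#' @examples
#' m <- generateCountMatrix(100, seed = 3, plantLowTranscripts = 5)
#' attr(m, "planted")$low_transcripts
#' @export
generateCountMatrix <- function(nCells, nGenes = 300, nMitoGenes = 30,
                                seed = 1, mitoFraction = 0.03,
                                plantLowTranscripts = 0, plantLowGenes = 0,
                                plantHighMito = 0, plantBoundary = 0) {
  nPlanted <- plantLowTranscripts + plantLowGenes + plantHighMito +
    plantBoundary
  if (nCells < nPlanted)
    nk_error("bad_config", "nCells smaller than number of planted cells")
  if (nGenes < 200 || nMitoGenes < 10 || nGenes - nMitoGenes < 170)
    nk_error("bad_config", "need >= 200 genes with >= 170 non-mitochondrial")
  with_seed(seed, {
    nNon <- nGenes - nMitoGenes
    g_non <- paste0("G", seq_len(nNon))
    g_mito <- paste0("MT-", seq_len(nMitoGenes))
    genes <- c(g_non, g_mito)
    mu_non <- 5
    mu_mito <- if (mitoFraction > 0)
      mitoFraction * nNon * mu_non / ((1 - mitoFraction) * nMitoGenes) else 0
    nBg <- nCells - nPlanted
    m <- matrix(0L, nrow = nGenes, ncol = nCells,
                dimnames = list(genes,
                                sprintf("cell%04d", seq_len(nCells))))
    if (nBg > 0) {
      m[seq_len(nNon), seq_len(nBg)] <-
        rnbinom(nNon * nBg, mu = mu_non, size = 10)
      if (mu_mito > 0)
        m[nNon + seq_len(nMitoGenes), seq_len(nBg)] <-
          rnbinom(nMitoGenes * nBg, mu = mu_mito, size = 10)
    }
    j <- nBg
    planted <- list(low_transcripts = character(0), low_genes = character(0),
                    high_mito = character(0), boundary = character(0))
    plant <- function(nm, n, vec) {
      for (i in seq_len(n)) {
        j <<- j + 1
        m[, j] <<- vec
        planted[[nm]] <<- c(planted[[nm]], colnames(m)[j])
      }
    }
    v <- integer(nGenes)  # 360 transcripts over 120 genes: fails only totals
    v[seq_len(120)] <- 3L
    plant("low_transcripts", plantLowTranscripts, v)
    v <- integer(nGenes)  # 800 transcripts over 80 genes: fails only genes
    v[seq_len(80)] <- 10L
    plant("low_genes", plantLowGenes, v)
    v <- integer(nGenes)  # 600 transcripts, 20% mitochondrial
    v[seq_len(160)] <- 3L
    v[nNon + seq_len(20)] <- 6L
    plant("high_mito", plantHighMito, v)
    v <- integer(nGenes)  # exactly 500 tx, 100 genes, 10% mito
    v[seq_len(90)] <- 5L
    v[nNon + seq_len(10)] <- 5L
    plant("boundary", plantBoundary, v)
    storage.mode(m) <- "integer"
    attr(m, "planted") <- planted
    m
  })
}
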