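## Plain-text pipeline configuration: INI-style `key = value` lines under
## [section] headers; `#` comments. Every key is validated against the
## known vocabulary — unknown keys are an error, never silently ignored.

.known_keys <- list(
  input = c("dir", "coordinate_scale"),
  simulate = c("seed", "n_fovs", "fov_width", "fov_height", "niche"),
  qc = c("min_counts", "control_prefixes"),
  gate = c("min_count", "rules_file"),
  enrich = c("k", "min_cells"),
  proximity = c("target", "threshold", "scope"),
  summarize = c("panel"))

#' Read a pipeline configuration file
#'
#' @param path Path to an INI-style config (sections \code{[input]},
#'   \code{[simulate]}, \code{[qc]}, \code{[gate]}, \code{[enrich]},
#'   \code{[proximity]}, \code{[summarize]}).
#' @return Nested named list of sections.
#' @seealso \code{\link{runPipeline}}, \code{\link{defaultConfig}}
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    nk_error("missing_file", paste0("config not found: ", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(); section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(.known_keys))
        nk_error("bad_config", paste0("unknown config section: [", section, "]"))
      cfg[[section]] <- cfg[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        nk_error("bad_config", paste0("key outside any section: ", ln))
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% .known_keys[[section]])
        nk_error("bad_config",
                 paste0("unknown key '", key, "' in section [", section, "]"))
      cfg[[section]][[key]] <- val
    } else nk_error("bad_config", paste0("cannot parse config line: ", ln))
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default pipeline configuration text
#'
#' All analysis defaults pre-populated and visible: k = 150 neighbors,
#' 20-cell type exclusion, 20 um Near/Far threshold, 20-count cell
#' filter, Neg/System probe prefixes, the builtin gates and the 8-gene
#' summary panel.
#'
#' @param seed Simulation seed written into the \code{[simulate]} section.
#' @return Character vector of config lines.
#' @export
defaultConfig <- function(seed = 1) {
  c("[simulate]",
    paste0("seed = ", seed),
    "n_fovs = 2",
    "fov_width = 500",
    "fov_height = 500",
    "niche = regTh17:IL36G_KC:15:0.8",
    "",
    "[qc]",
    "min_counts = 20",
    "control_prefixes = Neg;System",
    "",
    "[gate]",
    "min_count = 1",
    "",
    "[enrich]",
    "k = 150",
    "min_cells = 20",
    "",
    "[proximity]",
    "target = IL36G_KC",
    "threshold = 20",
    "scope = within_fov",
    "",
    "[summarize]",
    paste0("panel = ", paste(defaultPanel(), collapse = ",")))
}

num <- function(x) as.numeric(x)

#' Run the full analysis pipeline from a config file
#'
#' Chains the stages simulate (or read) -> QC -> gate -> neighborhood
#' enrichment -> proximity -> panel summary, writing every stage output
#' plus a JSON run manifest (package version, config checksum, seeds,
#' per-stage cell counts, timestamps, output files) into \code{outDir}.
#' Re-running with an identical config reproduces identical outputs
#' (manifest timestamps aside).
#'
#' @param configPath Path to the config file
#'   (\code{\link{readPipelineConfig}} format). If its \code{[input]}
#'   section names a flat-file directory that is read; otherwise the
#'   \code{[simulate]} section drives \code{\link{generateSpatial}}.
#' @param outDir Output directory (created if needed).
#' @param seed Optional integer overriding the config's simulation seed.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(configPath, outDir, seed = NULL) {
  cfg <- readPipelineConfig(configPath)
  if (!is.null(cfg$enrich$k) && any(num(strsplit(cfg$enrich$k, ",")[[1]]) < 1))
    nk_error("bad_config", "enrich k must be >= 1")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(tool = "nichekit",
                   version = as.character(packageVersion("nichekit")),
                   config = normalizePath(configPath),
                   config_md5 = unname(tools::md5sum(configPath)),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
                   stages = list(), outputs = character(0))
  outfile <- function(nm) file.path(outDir, nm)
  log_stage <- function(name, ...) {
    info <- list(...)
    manifest$stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
  }

  ## --- acquire data -------------------------------------------------
  if (!is.null(cfg$input$dir)) {
    ds <- readCosmx(cfg$input$dir,
                    coordinateScale = num(cfg$input$coordinate_scale %||% "1"))
    sim_seed <- NA_integer_
    log_stage("read", cells = ncol(ds), genes = nrow(ds))
  } else {
    sim_seed <- as.integer(seed %||% cfg$simulate$seed %||% 1)
    niches <- list()
    nspec <- cfg$simulate$niche %||% ""
    if (nzchar(nspec)) {
      parts <- strsplit(nspec, ":", fixed = TRUE)[[1]]
      if (length(parts) != 4)
        nk_error("bad_config",
                 "niche must be subset:anchor:radius:fraction")
      niches <- list(list(subset = parts[1], anchor = parts[2],
                          radius = num(parts[3]), fraction = num(parts[4])))
    }
    sc <- simConfig(seed = sim_seed,
                    nFovs = as.integer(cfg$simulate$n_fovs %||% 2),
                    fovSize = c(num(cfg$simulate$fov_width %||% 500),
                                num(cfg$simulate$fov_height %||% 500)),
                    niches = niches)
    gs <- generateSpatial(sc)
    ds <- gs$dataset
    write.csv(gs$truth, outfile("ground_truth.csv"), row.names = FALSE)
    manifest$outputs <- c(manifest$outputs, "ground_truth.csv")
    log_stage("simulate", seed = sim_seed, cells = ncol(ds), genes = nrow(ds))
  }
  manifest$seed <- sim_seed

  ## --- QC -----------------------------------------------------------
  th <- qcThresholds(
    minCosmxCounts = num(cfg$qc$min_counts %||% "20"),
    controlPrefixes = strsplit(cfg$qc$control_prefixes %||% "Neg;System",
                               ";")[[1]])
  qc <- filterCosmxCells(ds, th)
  ds <- qc$dataset
  writeQcReport(qc$report, outfile("qc_report.txt"))
  manifest$outputs <- c(manifest$outputs, "qc_report.txt")
  log_stage("qc", cells_in = qc$report$n_input,
            cells_out = qc$report$n_retained,
            genes_removed = qc$report$n_genes_removed)

  ## --- gating -------------------------------------------------------
  rules <- if (!is.null(cfg$gate$rules_file))
    readGatingRules(cfg$gate$rules_file)
  else builtinRules(minCount = num(cfg$gate$min_count %||% "1"))
  gr <- gateCells(ds, rules)
  writeGating(gr, outfile("gating.csv"))
  manifest$outputs <- c(manifest$outputs, "gating.csv")
  log_stage("gate", cells = nrow(gr$assignments),
            labels = paste(names(gr$counts), gr$counts, sep = ":",
                           collapse = ","))

  ## --- neighborhood enrichment (ground-truth labels) ----------------
  labels <- cellLabels(ds)
  if (all(is.na(labels)))
    nk_error("no_labels",
             "enrichment requires cell-type labels on the dataset")
  ks <- as.integer(strsplit(cfg$enrich$k %||% "150", ",")[[1]])
  minc <- num(cfg$enrich$min_cells %||% "20")
  for (k in ks) {
    em <- neighborhoodEnrichment(ds, labels, k = k, minCellsPerType = minc)
    fn <- sprintf("enrichment_k%d.csv", k)
    writeMatrixCSV(em, outfile(fn))
    manifest$outputs <- c(manifest$outputs, fn)
  }
  log_stage("enrich", k = paste(ks, collapse = ","), min_cells = minc)

  ## --- proximity ----------------------------------------------------
  prox <- proximityAnalysis(
    ds, gr, target = cfg$proximity$target %||% "IL36G_KC",
    nearThreshold = num(cfg$proximity$threshold %||% "20"),
    scope = cfg$proximity$scope %||% "within_fov")
  write.csv(prox, outfile("proximity.csv"), row.names = FALSE)
  props <- subsetProportions(prox)
  write.csv(props, outfile("proximity_summary.csv"), row.names = FALSE)
  tests <- comparePairwise(prox)
  write.csv(tests, outfile("proximity_tests.csv"), row.names = FALSE)
  manifest$outputs <- c(manifest$outputs, "proximity.csv",
                        "proximity_summary.csv", "proximity_tests.csv")
  log_stage("proximity", rows = nrow(prox))

  ## --- panel summary ------------------------------------------------
  panel <- strsplit(cfg$summarize$panel %||%
                      paste(defaultPanel(), collapse = ","), ",")[[1]]
  ps <- summarizePanel(ds, labels, panel = trimws(panel))
  write.csv(ps, outfile("panel_summary.csv"), row.names = FALSE)
  manifest$outputs <- c(manifest$outputs, "panel_summary.csv")
  log_stage("summarize", rows = nrow(ps))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
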