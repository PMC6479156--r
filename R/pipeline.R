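## Orchestration: one options object, a single in-memory driver (runOceub),
## the experiment harness (all-groups / taxonomic surrogate / no-phylogeny),
## and a file-based, manifest-checked pipeline runner used by the CLI.

#' Pipeline options
#'
#' One place for every tunable of the modelling chain. Seeds for the
#' stochastic stages are derived from `seed` by fixed small offsets so a
#' single integer reproduces the whole run.
#'
#' @param seed master RNG seed.
#' @param minRecordsForComposition cells need at least this many records to
#'   enter the beta-diversity/ordination stage (composition estimated from a
#'   handful of records is noise; kriging fills the remaining cells).
#' @param resample a [resampleConfig()] (seed is overridden).
#' @param krige a [krigeConfig()] (seed is overridden).
#' @param nmdsDim NMDS dimensionality for the species and phylogenetic
#'   composition ordinations.
#' @param nmdsRounds NMDS random restarts.
#' @param regionK number of regions, or `"auto"` for BIC selection.
#' @param regionKRange candidate counts for `"auto"`.
#' @param ga a [gaConfig()] (seed is overridden).
#' @param effortQuantile sampling-sufficiency cutoff quantile.
#' @param captureMode `"species"` (a species/branch counts as captured once
#'   any selected cell holds it) or `"cellsum"` (fractions are sums of the
#'   per-cell surface values over selected cells).
#' @param nRecords,bias defaults for synthetic sampling in
#'   [endToEndRecovery()].
#' @export
oceubOptions <- function(seed = 1,
                         minRecordsForComposition = 5,
                         resample = resampleConfig(),
                         krige = krigeConfig(),
                         nmdsDim = 3, nmdsRounds = 100,
                         regionK = "auto", regionKRange = 2:12,
                         ga = gaConfig(),
                         effortQuantile = 0.5,
                         captureMode = c("species", "cellsum"),
                         nRecords = 20000, bias = 0) {
  resample$seed <- seed + 11L
  krige$seed <- seed + 13L
  ga$seed <- seed + 17L
  structure(list(seed = as.integer(seed),
                 minRecordsForComposition = minRecordsForComposition,
                 resample = resample, krige = krige,
                 nmdsDim = nmdsDim, nmdsRounds = nmdsRounds,
                 regionK = regionK, regionKRange = regionKRange,
                 ga = ga, effortQuantile = effortQuantile,
                 captureMode = match.arg(captureMode),
                 nRecords = nRecords, bias = bias),
            class = "oceub_options")
}

# Presence matrix restricted to cells holding >= minRecords valid records.
.presenceSampledCells <- function(table, grid, minRecords) {
  pres <- assignCells(table, grid)
  counts <- vapply(recordsPerCell(table, grid), length, 1L)
  keep <- rownames(pres) %in% names(counts)[counts >= minRecords]
  if (sum(keep) < 4L) keep <- rep(TRUE, nrow(pres))   # tiny data: use all
  pres[keep, , drop = FALSE]
}

#' Build the biodiversity surfaces of the modelling chain
#'
#' Richness (resampled then kriged), weighted endemism (kriged), areas of
#' endemism (kernel consensus, not kriged), phylogenetic weighted endemism
#' (kriged), and the species/phylogenetic composition surfaces (NMDS axes of
#' the beta-diversity matrices, kriged to all cells).
#'
#' @param table an `occurrence_table` (the data the model is built from).
#' @param tree an `ape::phylo` with unit branch lengths.
#' @param grid a [HexGrid-class].
#' @param opts an [oceubOptions()].
#' @param phylo build the phylogenetic composition surfaces too?
#' @return list with `richness`, `endemism`, `aoe`, `pe`, `sci`, `ipc`,
#'   `richnessRaw`, `presence`.
#' @export
buildSurfaces <- function(table, tree, grid, opts = oceubOptions(),
                          phylo = TRUE) {
  presence <- assignCells(table, grid)
  richRaw <- richnessResampled(table, grid, opts$resample)
  rich <- krige(richRaw, grid, opts$krige)$prediction
  we <- krige(weightedEndemism(presence, grid), grid, opts$krige)$prediction
  aoe <- gieConsensus(speciesDispersion(table), grid)
  pe <- krige(pweSurface(presence, tree, grid), grid, opts$krige)$prediction
  presComp <- .presenceSampledCells(table, grid, opts$minRecordsForComposition)
  ordS <- nmdsOrdination(betaSorensen(presComp), ndim = opts$nmdsDim,
                         nRounds = opts$nmdsRounds, seed = opts$seed + 19L)
  sci <- compositionSurfaces(ordS, grid, opts$krige, prefix = "sci")
  ipc <- NULL
  if (phylo) {
    ordP <- nmdsOrdination(betaPhylosor(presComp, tree), ndim = opts$nmdsDim,
                           nRounds = opts$nmdsRounds, seed = opts$seed + 23L)
    ipc <- compositionSurfaces(ordP, grid, opts$krige, prefix = "ipc")
  }
  list(richness = rich, endemism = we, aoe = aoe, pe = pe,
       sci = sci, ipc = ipc, richnessRaw = richRaw, presence = presence)
}

#' Run the modelling chain in memory
#'
#' Ingest -> surfaces -> regionalization -> GA optimization -> quantization
#' -> sampling effort -> categorization, on one occurrence table. `mode`
#' selects the experiment variant: `"all_groups"` uses everything;
#' `"surrogate:<group>"` builds surfaces and regions from one taxon group
#' only but always evaluates fitness against all groups;
#' `"no_phylo"` drops phylogenetic composition from regionalization and the
#' phylogenetic-endemism weight from the summation, while the final report
#' still scores the captured branch length and phylogenetic endemism.
#'
#' @param table an `occurrence_table`.
#' @param tree an `ape::phylo` (branch lengths are reset to one).
#' @param grid a [HexGrid-class].
#' @param opts an [oceubOptions()].
#' @param mode `"all_groups"`, `"surrogate:<group>"` or `"no_phylo"`.
#' @return list of class `oceub_run` with surfaces, regions, GA output, the
#'   best fitness result, effort/sufficiency/categories and inputs.
#' @export
runOceub <- function(table, tree, grid, opts = oceubOptions(),
                     mode = "all_groups") {
  tree <- setUnitBranchLengths(tree)
  noPhylo <- identical(mode, "no_phylo")
  modelTable <- table
  if (startsWith(mode, "surrogate:")) {
    g <- sub("^surrogate:", "", mode)
    if (!any(table$group == g, na.rm = TRUE))
      stop("group absent from data: ", g)
    modelTable <- table[!is.na(table$group) & table$group == g, , drop = FALSE]
    class(modelTable) <- class(table)
  }
  surf <- buildSurfaces(modelTable, tree, grid, opts, phylo = !noPhylo)
  regions <- classifyRegions(c(surf$sci, surf$ipc), k = opts$regionK,
                             seed = opts$seed + 29L, kRange = opts$regionKRange)
  rescaled <- list(
    richness = rescaleWithinRegions(surf$richness, regions),
    endemism = rescaleWithinRegions(surf$endemism, regions),
    aoe = rescaleWithinRegions(surf$aoe, regions),
    pe = if (noPhylo) newSurface(grid, rep(0, nCells(grid)), "pe_unused")
         else rescaleWithinRegions(surf$pe, regions))
  presenceAll <- assignCells(table, grid)
  inputs <- fitnessInputs(presenceAll, tree, grid)
  fixGenome <- function(genome) {
    if (noPhylo) genome["w_pe"] <- 0
    genome
  }
  objective <- function(genome)
    evaluateFitness(fixGenome(genome), rescaled, inputs)$value
  ga <- gaOptimize(objective, opts$ga)
  ga$genome <- fixGenome(ga$genome)
  best <- evaluateFitness(ga$genome, rescaled, inputs)
  validPts <- table[table$valid_geo, c("lon", "lat"), drop = FALSE]
  effort <- kernelDensity(validPts, grid)
  sufficiency <- effortClasses(effort, rule = list(quantile = opts$effortQuantile))
  selected <- rep(FALSE, nCells(grid))
  selected[best$selected_cells + 1L] <- TRUE
  categories <- categorizeCells(selected, sufficiency, grid)
  structure(list(mode = mode, surfaces = surf[c("richness", "endemism", "aoe", "pe")],
                 sci = surf$sci, ipc = surf$ipc, richnessRaw = surf$richnessRaw,
                 rescaled = rescaled, regions = regions, ga = ga, best = best,
                 inputs = inputs, effort = effort, sufficiency = sufficiency,
                 categories = categories, opts = opts), class = "oceub_run")
}

#' @export
print.oceub_run <- function(x, ...) {
  cat(sprintf("oceub run (mode %s): %d regions, GA %d generations\n",
              x$mode, nRegions(x$regions), x$ga$generations))
  print(x$best)
  invisible(x)
}

#' Run one experiment mode and report it
#'
#' @param mode `"all_groups"`, `"surrogate:<group>"` or `"no_phylo"`.
#' @param data list with `occurrences`, `tree`, `grid`.
#' @param opts an [oceubOptions()].
#' @return list of class `oceub_experiment` with the run and a one-row
#'   summary (mode, fitness, captured fractions, area fraction).
#' @export
runExperiment <- function(mode, data, opts = oceubOptions()) {
  run <- runOceub(data$occurrences, data$tree, data$grid, opts, mode = mode)
  b <- run$best
  summary <- data.frame(mode = mode, fitness = b$value, r = b$r, pl = b$pl,
                        e = b$e, pe = b$pe, area_fraction = b$area_fraction)
  structure(list(run = run, summary = summary), class = "oceub_experiment")
}

#' Compare experiment modes
#' @param experiments list of [runExperiment()] results.
#' @return data.frame with one row per mode.
#' @export
compareExperiments <- function(experiments) {
  do.call(rbind, lapply(experiments, `[[`, "summary"))
}

## ---- file-based pipeline with manifests ----------------------------------

.writeManifest <- function(dir, step, params, inputs = character(0)) {
  man <- list(step = step,
              params_md5 = paramsDigest(params),
              inputs = as.list(if (length(inputs))
                vapply(inputs, function(f) unname(tools::md5sum(f)), "") else
                  character(0)))
  path <- file.path(dir, paste0("manifest-", step, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE)
  invisible(man)
}

.manifestCurrent <- function(dir, step, params, inputs = character(0)) {
  path <- file.path(dir, paste0("manifest-", step, ".json"))
  if (!file.exists(path)) return(FALSE)
  old <- jsonlite::read_json(path)
  if (!identical(old$params_md5, unname(paramsDigest(params)))) return(FALSE)
  cur <- if (length(inputs))
    lapply(inputs, function(f) unname(tools::md5sum(f))) else list()
  identical(unname(unlist(old$inputs)), unname(unlist(cur)))
}

#' Read a pipeline configuration file
#'
#' YAML key-value schema: `occurrences` (CSV path), `tree` (newick path),
#' `extent` (xmin, ymin, xmax, ymax), `cell_size_deg`, `seed`, `mode`, and
#' optional overrides for any [oceubOptions()] field plus `boundary`
#' (GeoJSON path).
#'
#' @param path YAML file.
#' @return list of class `pipeline_config`.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  for (p in c("occurrences", "tree"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured path does not exist: ", cfg[[p]])
  structure(cfg, class = "pipeline_config")
}

#' Run the pipeline from a configuration, writing step artifacts
#'
#' Each step writes its artifact plus a manifest (parameter digest and input
#' file checksums); a rerun with unchanged manifests skips recomputation
#' unless `force = TRUE`. Artifacts are plain cell tables and JSON.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param outdir output directory.
#' @param force recompute even when manifests are current.
#' @return (invisibly) the `oceub_run`, with artifact paths as attribute.
#' @export
runPipeline <- function(config, outdir, force = FALSE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  opts <- oceubOptions(seed = seed)
  for (nm in c("minRecordsForComposition", "nmdsDim", "nmdsRounds",
               "regionK", "effortQuantile", "nRecords", "bias"))
    if (!is.null(config[[nm]])) opts[[nm]] <- config[[nm]]
  mode <- config$mode %||% "all_groups"
  keyParams <- list(config = unclass(config), opts = unclass(opts), mode = mode)
  inputs <- c(config$occurrences, config$tree)
  final <- file.path(outdir, "categories.csv")
  if (!force && file.exists(final) &&
      .manifestCurrent(outdir, "run", keyParams, inputs)) {
    message("manifests current; skipping recomputation (use force = TRUE to rerun)")
    return(invisible(structure(list(outdir = outdir, skipped = TRUE),
                               class = "oceub_pipeline_result")))
  }
  table <- readOccurrences(config$occurrences,
                           dialect = c(species = "species", lon = "lon",
                                       lat = "lat", group = "group"))
  if (!is.null(config$boundary))
    table <- validateGeography(table, readBoundary(config$boundary))
  tree <- readNewick(config$tree)
  grid <- buildHexGrid(as.numeric(unlist(config$extent)),
                       config$cell_size_deg %||% 1)
  run <- runOceub(table, tree, grid, opts, mode = mode)

  utils::write.csv(cellTable(grid), file.path(outdir, "cells.csv"),
                   row.names = FALSE)
  surfTab <- cellTable(grid)
  for (nm in names(run$surfaces))
    surfTab[[nm]] <- surfaceValues(run$surfaces[[nm]])
  utils::write.csv(surfTab, file.path(outdir, "surfaces.csv"), row.names = FALSE)
  regTab <- cellTable(grid); regTab$region <- regionLabels(run$regions)
  utils::write.csv(regTab, file.path(outdir, "regions.csv"), row.names = FALSE)
  jsonlite::write_json(list(genome = as.list(unclass(run$ga$genome)),
                            fitness = run$ga$fitness,
                            generations = run$ga$generations,
                            seed = seed),
                       file.path(outdir, "genome.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(run$ga$history, file.path(outdir, "history.csv"),
                   row.names = FALSE)
  selTab <- cellTable(grid)
  selTab$selected <- (seq_len(nCells(grid)) - 1L) %in% run$best$selected_cells
  utils::write.csv(selTab, file.path(outdir, "selected.csv"), row.names = FALSE)
  effTab <- cellTable(run$effort)
  effTab$sufficient <- run$sufficiency
  utils::write.csv(effTab, file.path(outdir, "effort.csv"), row.names = FALSE)
  catTab <- cellTable(grid)
  catTab$category <- as.character(cellCategories(run$categories))
  utils::write.csv(catTab, file.path(outdir, "categories.csv"), row.names = FALSE)
  utils::write.csv(summarizeCategories(run$categories),
                   file.path(outdir, "summary.csv"), row.names = FALSE)
  .writeManifest(outdir, "run", keyParams, inputs)
  attr(run, "artifacts") <- list.files(outdir, full.names = TRUE)
  invisible(run)
}
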