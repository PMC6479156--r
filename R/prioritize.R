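## Weighted-sum prioritization and the genetic algorithm.
##
## The GA individual ("genome") is five alleles in [0,1]: weights for the
## richness, endemism, areas-of-endemism and phylogenetic-endemism surfaces,
## plus the quantization threshold that turns the weighted relevance map
## into a binary selection. Fitness is the mean captured fraction of
## species, branch length, endemism weight and phylogenetic endemism weight,
## minus the selected-area fraction.

GENOME_NAMES <- c("w_richness", "w_endemism", "w_aoe", "w_pe", "threshold")

#' Construct a GA genome
#' @param w_richness,w_endemism,w_aoe,w_pe surface weights in `[0, 1]`.
#' @param threshold quantization threshold in `[0, 1]`.
#' @return named numeric of class `oceub_genome`.
#' @export
newGenome <- function(w_richness = 0.5, w_endemism = 0.5, w_aoe = 0.5,
                      w_pe = 0.5, threshold = 0.5) {
  g <- c(w_richness, w_endemism, w_aoe, w_pe, threshold)
  if (any(g < 0 | g > 1)) stop("all alleles must lie in [0, 1]")
  names(g) <- GENOME_NAMES
  class(g) <- "oceub_genome"
  g
}

#' Rescale a surface to [0, 1] within each region
#'
#' Biotas of different regions are not comparable, so each biodiversity
#' variable is stretched to its own regional range before summation:
#' `(v - min) / (max - min)` per region. A constant region collapses to 0
#' with a warning; no-data cells and cells without a region label stay NA.
#'
#' @param surface a [Surface-class].
#' @param regions a [RegionMap-class] on the same grid.
#' @return a [Surface-class].
#' @export
rescaleWithinRegions <- function(surface, regions) {
  v <- surfaceValues(surface)
  lab <- regionLabels(regions)
  out <- rep(NA_real_, length(v))
  for (g in sort(unique(lab[!is.na(lab)]))) {
    ix <- which(lab == g & !is.na(v))
    if (!length(ix)) next
    rng <- range(v[ix])
    if (rng[2] - rng[1] <= 0) {
      warning(sprintf("region %d is constant in '%s'; rescaled to 0",
                      g, surfaceName(surface)))
      out[ix] <- 0
    } else {
      out[ix] <- (v[ix] - rng[1]) / (rng[2] - rng[1])
    }
  }
  newSurface(surface@grid, out, surfaceName(surface))
}

#' Weighted sum of the four biodiversity surfaces
#'
#' `w_richness * richness + w_endemism * WE + w_aoe * AoE + w_pe * PE`,
#' min-max rescaled to `[0, 1]` globally afterwards so the threshold allele
#' is comparable across genomes. All-zero weights yield an all-zero surface
#' with a warning.
#'
#' @param surfaces named list with elements `richness`, `endemism`, `aoe`,
#'   `pe` (already rescaled within regions).
#' @param genome an [newGenome()] genome (threshold allele ignored here).
#' @return a [Surface-class] in `[0, 1]`.
#' @export
weightedSum <- function(surfaces, genome) {
  need <- c("richness", "endemism", "aoe", "pe")
  if (!all(need %in% names(surfaces)))
    stop("surfaces must be named richness, endemism, aoe, pe")
  w <- as.numeric(genome)[1:4]
  grid <- surfaces[[1]]@grid
  acc <- rep(0, nCells(grid))
  na <- rep(FALSE, nCells(grid))
  for (i in 1:4) {
    v <- surfaceValues(surfaces[[need[i]]])
    na <- na | is.na(v)
    acc <- acc + w[i] * ifelse(is.na(v), 0, v)
  }
  acc[na] <- NA_real_
  if (all(w == 0)) {
    warning("all weights are zero; relevance surface is all zero")
    acc[!na] <- 0
    return(newSurface(grid, acc, "relevance"))
  }
  newSurface(grid, rescale01(acc), "relevance")
}

#' Threshold a relevance surface into a binary selection
#'
#' @param surface a [Surface-class] in `[0, 1]`.
#' @param threshold selection cutoff; a cell is selected iff its value is
#'   `>= threshold`. No-data cells are never selected.
#' @return logical vector per cell.
#' @export
quantizeSurface <- function(surface, threshold) {
  v <- surfaceValues(surface)
  !is.na(v) & v >= threshold
}

#' Precompute the quantities the fitness function needs
#'
#' @param presence logical presence matrix from [assignCells()] (always the
#'   full, all-groups data: surrogate models are evaluated against all
#'   groups).
#' @param tree an `ape::phylo` with unit branch lengths.
#' @param grid the analysis [HexGrid-class].
#' @param nTotalCells total area `A` in cells (defaults to `nCells(grid)`).
#' @return list of class `fitness_inputs`.
#' @export
fitnessInputs <- function(presence, tree, grid, nTotalCells = nCells(grid)) {
  ce <- cellEdgeIncidence(presence, tree)
  len <- attr(ce, "edge.length")
  rb <- colSums(ce)
  present <- rb > 0
  weS <- 1 / colSums(presence)
  structure(list(
    presence = presence,
    cellIds = as.integer(rownames(presence)),
    cellEdge = ce[, present, drop = FALSE],
    edgeLength = len[present],
    peWeight = len[present] / rb[present],
    weSpecies = weS,
    nTotalCells = nTotalCells), class = "fitness_inputs")
}

#' Captured fractions of a selected cell set
#'
#' `r` = fraction of species with at least one selected occupied cell;
#' `pl` = fraction of total branch length captured; `e` = fraction of total
#' endemism weight carried by captured species; `pe` = fraction of total
#' phylogenetic endemism weight carried by captured branches;
#' `area_fraction` = selected cells / total cells.
#'
#' @param selected logical per grid cell (or integer cell ids).
#' @param inputs a [fitnessInputs()] object.
#' @return named numeric `(r, pl, e, pe, area_fraction)`.
#' @export
coverageFractions <- function(selected, inputs) {
  if (is.logical(selected)) {
    selIds <- which(selected) - 1L
    nSel <- sum(selected)
  } else {
    selIds <- as.integer(selected)
    nSel <- length(selIds)
  }
  rows <- inputs$cellIds %in% selIds
  if (any(rows)) {
    spCap <- colSums(inputs$presence[rows, , drop = FALSE]) > 0
    brCap <- colSums(inputs$cellEdge[rows, , drop = FALSE]) > 0
  } else {
    spCap <- rep(FALSE, ncol(inputs$presence))
    brCap <- rep(FALSE, ncol(inputs$cellEdge))
  }
  c(r = mean(spCap),
    pl = sum(inputs$edgeLength[brCap]) / sum(inputs$edgeLength),
    e = sum(inputs$weSpecies[spCap]) / sum(inputs$weSpecies),
    pe = sum(inputs$peWeight[brCap]) / sum(inputs$peWeight),
    area_fraction = nSel / inputs$nTotalCells)
}

#' Evaluate the fitness of a genome
#'
#' Composes weighted summation, thresholding and coverage accounting:
#' `value = (r + pl + e + pe) / 4 - area_fraction`, always in `[-1, 1]`.
#' A model capturing everything in a vanishing area approaches 1; selecting
#' every cell scores exactly 0.
#'
#' @param genome a [newGenome()] genome.
#' @param surfaces named list (`richness`, `endemism`, `aoe`, `pe`) of
#'   surfaces already rescaled within regions.
#' @param inputs a [fitnessInputs()] object.
#' @return list of class `fitness_result`: `value`, the four fractions,
#'   `area_fraction`, and the selected cell ids.
#' @export
evaluateFitness <- function(genome, surfaces, inputs) {
  rel <- weightedSum(surfaces, genome)
  sel <- quantizeSurface(rel, as.numeric(genome)[5])
  fr <- coverageFractions(sel, inputs)
  value <- mean(fr[c("r", "pl", "e", "pe")]) - fr[["area_fraction"]]
  stopifnot(abs(value - ((fr[["r"]] + fr[["pl"]] + fr[["e"]] + fr[["pe"]]) / 4 -
                           fr[["area_fraction"]])) < 1e-12)
  structure(list(value = value,
                 r = fr[["r"]], pl = fr[["pl"]], e = fr[["e"]], pe = fr[["pe"]],
                 area_fraction = fr[["area_fraction"]],
                 selected_cells = which(sel) - 1L,
                 genome = genome),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf(paste0("fitness %.4f  (r %.3f, pl %.3f, e %.3f, pe %.3f; ",
                     "area %.1f%% of cells)\n"),
              x$value, x$r, x$pl, x$e, x$pe, 100 * x$area_fraction))
  invisible(x)
}

#' Genetic algorithm configuration
#'
#' Defaults follow the published search setup where stated (population of
#' 20, up to 100 generations, bounds 0..1, the all-0.5 primeval gene seeding
#' the population, elitist selection plus random picks for diversity); the
#' operator rates themselves are tunable.
#'
#' @param popSize individuals per generation.
#' @param maxGenerations generation cap.
#' @param eliteFraction fraction of top-ranked individuals kept.
#' @param randomPickFraction fraction of additional random survivors.
#' @param crossoverRate probability a child is a uniform crossover of its
#'   two parents (otherwise a clone of the first).
#' @param mutationRate per-allele mutation probability.
#' @param mutationSd Gaussian mutation step (clipped to bounds).
#' @param stallGenerations stop when the best fitness has not improved for
#'   this many generations.
#' @param seed RNG seed.
#' @export
gaConfig <- function(popSize = 20, maxGenerations = 100, eliteFraction = 0.25,
                     randomPickFraction = 0.15, crossoverRate = 0.9,
                     mutationRate = 0.2, mutationSd = 0.1,
                     stallGenerations = 15, seed = 1) {
  stopifnot(popSize >= 2, maxGenerations >= 1)
  structure(list(popSize = as.integer(popSize),
                 maxGenerations = as.integer(maxGenerations),
                 eliteFraction = eliteFraction,
                 randomPickFraction = randomPickFraction,
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 mutationSd = mutationSd,
                 stallGenerations = as.integer(stallGenerations),
                 seed = as.integer(seed)), class = "ga_config")
}

#' Genetic-algorithm search over the five-allele genome
#'
#' Population-based maximization of `objective` on `[0, 1]^5`. Individual 0
#' of the initial population is the primeval gene `(0.5, ..., 0.5)`, the
#' rest are uniform draws. Each generation keeps the top-ranked elite plus a
#' random pick of survivors, and refills the population with uniform
#' crossover of selected parents followed by clipped Gaussian mutation.
#' Elitism guarantees the best-so-far is never lost, so the best-fitness
#' history is nondecreasing; the whole run is reproducible from the seed.
#'
#' @param objective function taking a genome (named numeric length 5) and
#'   returning a scalar fitness to maximize.
#' @param cfg a [gaConfig()].
#' @return list: `genome` (best), `fitness`, `history` (data.frame with
#'   per-generation best/mean), `generations` run.
#' @export
gaOptimize <- function(objective, cfg = gaConfig()) {
  set.seed(cfg$seed)
  p <- cfg$popSize
  nall <- length(GENOME_NAMES)
  pop <- matrix(stats::runif(p * nall), p, nall)
  pop[1, ] <- 0.5                       # primeval gene
  colnames(pop) <- GENOME_NAMES
  evalPop <- function(P) apply(P, 1, function(g) {
    objective(structure(g, names = GENOME_NAMES, class = "oceub_genome"))
  })
  fit <- evalPop(pop)
  bestFit <- -Inf; bestGenome <- NULL
  history <- data.frame(generation = integer(), best = numeric(), mean = numeric())
  stall <- 0L
  nElite <- max(1L, round(cfg$eliteFraction * p))
  nRand <- min(p - nElite, round(cfg$randomPickFraction * p))
  gen <- 0L
  repeat {
    gen <- gen + 1L
    imp <- max(fit) > bestFit + 1e-12
    if (max(fit) > bestFit) {
      bestFit <- max(fit)
      bestGenome <- pop[which.max(fit), ]
    }
    stall <- if (imp) 0L else stall + 1L
    history <- rbind(history, data.frame(generation = gen, best = bestFit,
                                         mean = mean(fit)))
    if (gen >= cfg$maxGenerations || stall >= cfg$stallGenerations) break
    ord <- order(fit, decreasing = TRUE)
    elites <- ord[seq_len(nElite)]
    rest <- setdiff(ord, elites)
    picks <- if (nRand > 0 && length(rest)) sample(rest, min(nRand, length(rest)))
             else integer(0)
    parents <- c(elites, picks)
    nChild <- p - length(parents)
    children <- matrix(NA_real_, nChild, nall)
    if (nChild > 0) {
      for (ci in seq_len(nChild)) {
        pr <- sample(parents, 2, replace = TRUE)
        child <- if (stats::runif(1) < cfg$crossoverRate) {
          mask <- stats::runif(nall) < 0.5
          ifelse(mask, pop[pr[1], ], pop[pr[2], ])
        } else pop[pr[1], ]
        mut <- stats::runif(nall) < cfg$mutationRate
        child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = cfg$mutationSd)
        children[ci, ] <- pmin(1, pmax(0, child))
      }
      newPop <- rbind(pop[parents, , drop = FALSE], children)
      newFit <- c(fit[parents], evalPop(children))
    } else {
      newPop <- pop[parents, , drop = FALSE]
      newFit <- fit[parents]
    }
    colnames(newPop) <- GENOME_NAMES
    pop <- newPop
    fit <- newFit
  }
  list(genome = structure(bestGenome, names = GENOME_NAMES, class = "oceub_genome"),
       fitness = bestFit, history = history, generations = gen)
}
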