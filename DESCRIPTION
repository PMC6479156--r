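Package: oceub
Title: Optimizing Combined Evidences in Unique Biota for Spatial
    Conservation Prioritization
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit mapping of highly biodiverse areas from
    species occurrence records and phylogenies. Builds per-cell
    biodiversity surfaces on a hexagonal grid (resampled species
    richness, weighted endemism, geographic interpolation of endemism,
    phylogenetic weighted endemism), regionalizes the study area into
    biogeographic units of unique species and lineage composition via
    non-metric multidimensional scaling of (phylogenetic) beta
    diversity followed by Gaussian maximum-likelihood classification,
    and optimizes a weighted combination of the surfaces with a genetic
    algorithm so that the smallest possible area captures the most
    species, branch length, endemism and phylogenetic endemism.
    Sampling effort is modelled explicitly by kernel density so that
    cells with insufficient information are flagged rather than
    misclassified. Includes a synthetic landscape generator with
    planted regions, endemism hotspots and biased sampling for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    vegan,
    MASS,
    mclust,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
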