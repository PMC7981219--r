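Package: sympatria
Title: Congeneric Sympatry, Bioregions and Body-Size Divergence from
    Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for occurrence-based analysis of congeneric sympatry and
    body-size divergence in species-rich clades. Cleans point occurrences
    against range polygons, bins them on an adaptive quadtree grid, partitions
    the species-by-cell bipartite network into bioregions, applies a directed
    distance-threshold sympatry rule, computes a signed chi-squared "divergent
    sympatry" statistic against genus-wide size-class expectations, measures
    assemblage phylogenetic dispersion (MPD with standardized effect sizes
    under a tip-shuffling null), and fits Brownian-motion, Ornstein-Uhlenbeck
    and early-burst trait models with Pagel's lambda, ancestral states and
    PGLS residuals. Includes a synthetic-data generator (Yule trees, Brownian
    traits, disc ranges with a controllable co-occurrence design, occurrence
    clouds, elevation and biome rasters) so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    phytools,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
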