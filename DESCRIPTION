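Package: nichescape
Title: Linking Assemblage Species Richness to Climatic Niche Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking geographic patterns of assemblage-level
    species richness to the climatic niche properties of co-occurring species.
    Niches are modelled as minimum-volume ellipsoids in a principal-component
    climate space, projected to geography, constrained by convex-hull buffers,
    and assembled into a presence-absence matrix from which richness and
    per-cell mean niche breadth, marginality and phylogenetic niche position
    are mapped. Continuous-trait models (Brownian motion, Ornstein-Uhlenbeck,
    early burst, rate trend) are fitted to niche centroids on a phylogeny to
    reconstruct the ancestral niche, and richness-property relationships are
    tested with simultaneous autoregressive spatial error models against
    spreading-dye geometric-constraint and property-shuffle null models.
    A seeded synthetic-scenario generator (autocorrelated climate landscapes,
    birth-death phylogenies, niches evolved under Ornstein-Uhlenbeck dynamics,
    occurrence sampling) makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
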