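Package: ctcoloc
Title: Spatial Colocalization of Lifespan Cortical Thickness Change with
    Neurobiological Marker Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to relate spatial patterns of cortical thickness (CT)
    change across the lifespan to parcellated neurobiological marker maps
    (receptor densities, cell-type gene expression, microstructure).
    Implements parcel-map containers and I/O, factor-analytic reduction of
    atlas libraries (minimum-residual extraction, promax rotation),
    sliding-window relative CT change maps from normative trajectories,
    variogram-matched spatially autocorrelated surrogate maps for empirical
    inference, univariate and multivariate explained-variance scans,
    exhaustive dominance analysis with surrogate-based significance,
    regional influence maps, validation against developmental gene
    expression trajectories, transfer to longitudinal single-subject
    cohorts, and seeded synthetic-data generators with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
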