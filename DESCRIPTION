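Package: porescape
Title: Spatial Organization of Membrane-Protein Pores from AFM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the supramolecular organization of membrane proteins
    (beta-barrel pores such as VDAC1) in supported lipid bilayers imaged by
    atomic force microscopy. Provides boundary-corrected radial distribution
    functions normalized by the ring-patch intersection, distance-context
    classification of pairwise contacts, density-based cluster statistics,
    pore localization in topography images by normalized cross-correlation
    with tiered confidence sets, construction of coarse-grained protein-lipid
    assembly models at measured coordinates with rotational clash minimization
    and sequential lipid pruning, lipid occupancy/enrichment maps on a fine
    grid, and membrane composition bookkeeping. A synthetic-data module
    generates glassy honeycomb packings, filament chains, dense aggregates,
    Poisson controls, rendered topographies and disc-and-shell templates so
    the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
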