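Package: prairiescape
Title: Airborne Remote Sensing of Prairie Restoration: Synthetic Scenes,
    Surface Temperature Retrieval and Diversity-Energy-Balance Linkage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking grassland restoration treatments to airborne
    measures of biodiversity, productivity and surface energy balance. The
    package generates fully specified synthetic prairie scenes (experiment
    layout, quadrat species cover, endmember-mixed VNIR reflectance and a
    surface temperature field, forward-simulated to at-sensor imagery),
    calibrates at-sensor VNIR radiance to reflectance with an empirical line
    anchored on calibration tarps, computes NDVI, Water Band Index and VNIR
    albedo rasters, retrieves broadband land surface temperature with a
    tarp-anchored single-channel method using NDVI-threshold emissivity,
    derives quadrat diversity metrics (richness, Shannon indices, functional
    groups, Bray-Curtis distances), and fits the grouped regressions and
    ANCOVA contrasts that relate diversity and composition to the airborne
    indices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
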