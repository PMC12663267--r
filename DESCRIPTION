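Package: hemirad
Title: Synthetic Hemispheric Images, Sky-View Factor and Direct-Beam
    Transmissivity from Terrain and Canopy Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computes potential light availability at the ground surface
    from digital terrain models and a canopy height model. Terrain horizon
    lines (two-stage local/regional scan) and ray-traced canopy thickness
    are combined into synthetic binary hemispheric images, from which two
    sky-view-factor variants (planar and hemispheric receiver) and
    time-resolved direct-beam transmissivity along a NOAA solar track are
    derived. Canopy light penetration follows an exponential path-length
    law with a per-pixel effective foliage area volume density interpolated
    from an evergreen/deciduous mix-rate raster, with separate leaf-on and
    leaf-off states. Includes a synthetic-scene generator with analytic
    ray-marching oracles, GeoTIFF and NetCDF input/output with 8-bit
    percentage encoding, and a mask-driven pipeline producing the
    terrain/leaf-on/leaf-off layer set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ncdf4,
    stats,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
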