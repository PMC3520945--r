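Package: tinterrain
Title: Multi-Scale Rugosity, Slope and Aspect from Triangulated Terrain
    Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Terrain-complexity geomorphometry for fine-scale bathymetric
    reconstructions represented as triangulated irregular networks (TINs).
    Computes virtual chain-tape rugosity along transects, windowed
    area-based rugosity with projection onto either the horizontal plane
    or the PCA plane of best fit (which decouples rugosity from slope),
    and slope, aspect, northness and eastness at multiple window sizes.
    Includes mesh input/output for PLY, OBJ and STL, Delaunay
    triangulation of 2.5D point clouds, seeded synthetic terrain
    generators with known analytic structure, and the placement-sensitivity
    and correlation machinery used to validate the measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
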