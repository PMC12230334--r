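Package: sicmorph
Title: Morphometry and Morphodynamics of Scanning Ion Conductance
    Microscopy Topographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of forward/backward scan pairs from scanning ion
    conductance microscopy (SICM) of isolated organelles such as
    mitochondria. Provides the standard preprocessing chain for hopping-mode
    height maps (scanline alignment by row medians or medians of row
    differences, mean-plane levelling, zero-floor), single-scan shape
    descriptors (projected roundness and shape classification, volume by
    height integration, surface area by triangulation, the modified
    mitochondrial complexity index MCI*), forward/backward difference
    images and the total edge volume (TEV) morphodynamics statistic with
    its linear time trend and zero-crossing extrapolation, detection of
    height-intermittency dropout events along fast-axis line profiles,
    and a fully seeded synthetic scan-pair generator that provides ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
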