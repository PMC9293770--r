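Package: phagomotion
Title: Motion-State Analysis of Intracellular Cargo Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of motor-driven intracellular cargo
    transport, built around bead-phagosome tracking in macrophages.
    Generates labelled two-state (directed/diffusive) trajectories and
    synthetic image stacks, recovers sub-pixel tracks by centroid
    localization, classifies motion states by sliding-window mean-square
    displacement scaling exponents with a two-Gaussian cutoff, parses
    directed motion into constant-velocity runs by penalized change-point
    detection, and summarises transport statistics (percent directed
    motion, run length, velocity, dissociation rate) with group
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
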