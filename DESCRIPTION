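Package: magswim
Title: Magnetotactic Bacteria Swimming in Sediment-Like Obstacle Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for magnetotactic bacteria
    navigating quasi-2D sediment-mimicking obstacle channels. Implements a
    dipolar active Brownian particle model with Weeks-Chandler-Andersen
    obstacle repulsion and a phenomenological surface torque, integrated by
    the Euler-Maruyama method in a compiled core; a synthetic sediment
    generator with grain and water-gap granulometry on binary masks;
    channel-transit analyses (arrival curves, density heat maps, throughput
    ratios, field sweeps); sliding-distance extraction and calibration of
    the surface-torque length; and trap-escape experiments with exponential
    escape-time fits against field strength and trap depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
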