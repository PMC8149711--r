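Package: ncckit
Title: Nanosensor Chemical Cytometry of Single-Cell Hydrogen Peroxide Efflux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification toolkit for nanosensor chemical cytometry (NCC):
    label-free cytometry in which cells flowing over a near-infrared
    fluorescent carbon-nanotube sensor array are detected through their
    photonic-nanojet lensing images while the array reports their hydrogen
    peroxide efflux through fluorescence quenching. Implements the
    equilibrium sensor-response (Hill-type) calibration model with limit of
    detection and response time, the diffusion-reaction efflux field and
    sensor binding kinetics with trace-to-concentration inversion, a
    Lorenz-Mie near-field and scalar angular-spectrum forward model of
    cellular lensing with refractive-index estimation, the image-analysis
    pipeline (blob detection, patch normalization, shape statistics, trace
    extraction), a ground-truthed synthetic time-lapse generator, and
    population-level cytometry statistics (group comparisons, bimodality,
    kernel density estimates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    mclust,
    MASS,
    EBImage,
    tiff,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
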