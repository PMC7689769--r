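Package: halbachmri
Title: Design and Simulation of Halbach-Array Low-Field MRI Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design-and-simulation toolkit for permanent-magnet low-field
    magnetic resonance imaging systems built around discretized Halbach
    arrays. Computes magnetostatic fields of cube-magnet assemblies by
    point-dipole summation and of wire coils by Biot-Savart integration;
    optimizes ring diameters and ternary shim-magnet grids for field
    homogeneity with a genetic algorithm; designs transverse-field gradient
    coils on cylindrical formers with a target-field (stream-function)
    method and quantifies their efficiency and nonlinearity; models
    turbo-spin-echo acquisitions (elliptical k-space coverage, echo-train
    ordering, scan time, field drift, point-spread-function arithmetic);
    simulates Cartesian k-space acquisition of digital phantoms under
    nonlinear encoding fields; and reconstructs images by inverse FFT or by
    conjugate-phase summation that corrects gradient-nonlinearity and
    off-resonance distortion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
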