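Package: sdhspike
Title: Spiking-Pattern Mapping and Ion-Channel Density Inference for
    Superficial Dorsal Horn Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Conductance-based modelling of spiking-pattern heterogeneity in
    spinal superficial dorsal horn neurons. Simulates a modified Morris-Lecar
    neuron carrying a low-threshold (Kv1-type) and an inactivating (A-type)
    potassium conductance, classifies voltage responses into five spiking
    patterns (tonic, single, delayed, gap, reluctant) from inter-spike
    intervals, and maps pattern regions over the two-dimensional plane of
    potassium conductance densities. Population-level tools integrate a
    bivariate normal distribution of channel densities over the pattern map
    to predict spiking-pattern proportions, and invert that calculation with
    an iterative centroid-vector algorithm that estimates the distribution
    parameters (means, correlation, and standard deviations via grid search)
    from observed proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
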