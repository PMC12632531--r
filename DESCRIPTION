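Package: feverspike
Title: Thermal Challenge Electrophysiology: Evoked-Response Features,
    Neuron Fates, and Unit Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how cortical pyramidal neurons
    maintain evoked spiking as temperature rises into the fever range.
    Provides a seeded synthetic-data generator for intracellular voltage
    sweeps, extracellular single units and body-temperature series;
    extraction of per-sweep features (spike threshold by the second
    derivative criterion, PSP components, rheobase, input resistance);
    STAY/STOP/START/NEVER neuron-fate classification with exact binomial
    proportion tests; trough-to-peak waveform classification of single
    units with Hartigan's dip test and exact one-dimensional 2-means; and
    period firing-rate analysis for baseline/fever/recovery designs.
    Statistical primitives (dip test, exact two-tailed binomial test,
    correlation tests, Deming regression, two-sample Kolmogorov-Smirnov)
    are implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    knitr
Config/testthat/edition: 3
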