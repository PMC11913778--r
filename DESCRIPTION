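Package: gabashunt
Title: Shunting GABA-A Inhibition: Reversal-Potential Estimation, Spike-Train
    Metrics, and Balanced Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying fast synaptic inhibition in cortical
    neurons. Estimates the GABA-A receptor equilibrium potential (E_GABAAR),
    resting membrane potential and ionic driving force from voltage-clamp
    ramp and step protocols with offline series-resistance correction;
    summarises current-clamp recordings (membrane-potential densities,
    subthreshold fluctuation rates, response polarity); computes per-neuron
    trial-to-trial synchrony, peri-stimulus histogram entropy, evoked rates
    and k-nearest-neighbour population decoding on stimulus-aligned spike
    rasters; simulates a recurrent conductance-based integrate-and-fire
    network with homeostatic inhibitory plasticity to contrast shunting and
    hyperpolarizing inhibition; and solves a passive multicompartment cable
    model of the voltage-clamp experiment to quantify series-resistance bias
    in reversal-potential estimates. Seeded synthetic-data generators emulate
    every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    class,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    patchwork
Config/testthat/edition: 3
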