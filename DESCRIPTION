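Package: kv3net
Title: Kv3 Channel Gating, Fast-Spiking Interneuron Models, and Gamma-Band
    Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation and analysis toolkit for studying how
    biophysical modulation of Kv3 potassium channels shapes the excitability of
    fast-spiking parvalbumin (PV) interneurons and, downstream, the activity of
    a reduced cortical circuit.  Provides Kv3/Nav/Kv7/leak gating mechanisms
    with voltage-shift and kinetic-scale knobs, single-compartment PV and
    bursting pyramidal cell models, declarative stimulation protocols
    (current steps, voltage-clamp families, synaptic bombardment, dynamic-clamp
    conductance injection, gEPSP trains), a 220-cell recurrent network with gap
    junctions and an LFP proxy with gamma-band spectral analysis, Boltzmann and
    exponential curve fitting, and a synthetic patch-clamp data generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
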