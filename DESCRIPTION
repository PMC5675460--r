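Package: thalamosim
Title: Conductance-Based Thalamic Network Simulation of State-Dependent
    Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical (Hodgkin-Huxley) simulation of the thalamic circuit
    formed by the lateral geniculate nucleus and the reticular nucleus, with
    four cell classes (high-threshold bursting and relay-mode thalamocortical
    cells, local interneurons, and reticular neurons) coupled by chemical
    synapses with short-term depression and by gap junctions.  Two control
    parameters - the cholinergic/noradrenergic modulation level acting on
    potassium leak conductances, and the strength of afferent Poisson drive -
    move the network between delta, spindle, alpha/theta and gamma/beta
    oscillatory states.  The package provides the network constructor,
    a fixed-step Runge-Kutta simulation engine, stimulation protocols
    (spindle trigger, periodic pulse trains), and the analysis toolchain
    (simulated local field potential, power spectra, spike phases and
    synchronization index, burst statistics, oscillatory-state
    classification, entrainment and resonance profiling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
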