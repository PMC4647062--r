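Package: fxsephys
Title: Patch-Clamp Feature Extraction, K+ Current Decomposition and a
    Conductance-Based Simulator for Prefrontal Layer-5 Neuron Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing current-clamp and voltage-clamp
    recordings from cortical pyramidal neurons: subthreshold membrane
    properties (input resistance, sag, rebound, membrane time constant,
    ZAP impedance and resonance, temporal summation), action-potential
    threshold dynamics (dV/dt-criterion threshold, just-threshold
    strength-duration search, phase-plane analysis), and outside-out
    patch voltage-clamp analysis (leak subtraction, three-protocol
    decomposition of the total K+ current into fast-inactivating,
    slowly-inactivating and sustained components, Boltzmann activation
    fits, inactivation and recovery kinetics, h-current step analysis,
    drug-subtraction currents). A conductance-based one/two-compartment
    neuron and excised-patch simulator with wild-type and fmr1-knockout
    pyramidal-tract/intratelencephalic presets generates synthetic
    cohorts so the whole analysis chain runs with no experimental data,
    and a cohort pipeline applies the ANOVA/t-test battery with
    Bonferroni correction and effect sizes to produce genotype-by-class
    direction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
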