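Package: tcmass
Title: Thalamocortical Neural Mass Model with Excitatory Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simulation and dynamical analysis of a six-population
    thalamocortical neural mass model that adds an excitatory-interneuron
    (spiny stellate) population to the classical pyramidal, fast/slow
    inhibitory, thalamic relay and reticular circuit.  Provides a fixed-step
    fourth-order Runge-Kutta simulator with sinusoidal cortical and sensory
    drives, spectral and extrema-based feature extraction, rule-based
    classification of normal, preictal and seizure-like activity regimes,
    equilibrium continuation with Hopf bifurcation localization by
    eigenvalue bisection, one-dimensional bifurcation sweeps with
    period-doubling and bistability detection, two-dimensional state maps,
    and frequency-response analysis with resonance and amplitude-jump
    detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
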