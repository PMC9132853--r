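Package: myomag
Title: Forward Simulation of Skeletal Muscle EMG and MMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Systemic multi-scale forward model of the electric and magnetic
    fields generated by skeletal muscle activity. A homogenised multi-domain
    (bidomain-type) reaction-diffusion model with Hodgkin-Huxley membrane
    kinetics yields transmembrane and extracellular potentials on a structured
    finite-difference grid; an inactive-tissue (fat) volume conductor and a
    magnetostatic vector-potential solver produce surface electromyography
    (EMG) and magnetomyography (MMG) recordings at virtual sensors. Includes
    the in-silico spatial-selectivity experiment protocol (activation-depth
    sweeps, subcutaneous-fat sweeps, multi-channel RMS profiles), the
    decomposition of the magnetic field into per-domain contributions, and
    RMS/PSD/mean-frequency signal analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    methods,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
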