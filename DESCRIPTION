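Package: dermalCPM
Title: Cellular Potts Simulation of Senescent-Cell Dynamics in Dermal Wound
    Healing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lattice-based (Cellular Potts) multiscale simulator of dermal
    wound healing with explicit senescent-cell dynamics. Generalised cells
    (fibroblasts, myofibroblasts, macrophages, senescent myofibroblasts,
    pre-existing inflammatory senescent cells and one-pixel extracellular
    matrix) move by Metropolis pixel-copy dynamics on a 2-D lattice and
    interact through four diffusible fields (PDGF, CSF1, MMP and an
    inflammatory SASP field) integrated by an explicit finite-difference
    scheme with no-flux boundaries. Cell behaviour includes Monod growth,
    contact-inhibited proliferation, mitosis, PDGF-driven activation and
    myofibroblast differentiation, ECM deposition and MMP-mediated
    degradation, TIMP inhibition, macrophage M1/M2 polarisation, and primary
    (CCN1), juxtacrine and paracrine senescence with a two-phase
    (fibrogenic/fibrolytic) secretory programme. The package orchestrates
    healthy, chronic and fibrotic repair scenarios, a 5x5 sensitivity sweep
    over senescence probability and induction time, and particle swarm
    optimisation of threshold parameters against calibration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
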