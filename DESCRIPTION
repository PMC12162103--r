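Package: tmedyn
Title: Cellular-Molecular Dynamics of the Head and Neck Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A rule-based ordinary differential equation simulator of the
    head and neck squamous cell carcinoma (HNSCC) tumor microenvironment.
    Assembles a 24-state cell-state / cytokine network from declarative flux
    rules (logistic proliferation, first-order conversion, Hill-type
    paracrine amplification, regulatory inhibition, mass-action elimination,
    death and degradation), integrates it to steady state with stiff
    solvers, classifies steady states into the five clinically observed
    tumor-microenvironment subtypes, and runs in-silico interventions
    (anti-PD1 checkpoint inhibition, one-time IL-2 spikes, cytokine
    knockouts) together with parameter sweeps, a proliferation-to-death
    balance metric, local sensitivity analysis and biomarker readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    igraph
Config/testthat/edition: 3
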