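Package: immunosero
Title: Coupled Immune-Serotonin-Cortical Mean-Field Model of Inflammation-Linked Depression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic dynamic mean-field simulator of two reciprocally coupled
    cortical regions (prefrontal cortex and subcallosal cingulate cortex), each
    with excitatory and inhibitory populations gated by NMDA and GABA synaptic
    variables, driven by serotonergic currents whose amplitude follows the
    extracellular serotonin concentration. Serotonin synthesis and
    Michaelis-Menten reuptake are modulated by a cytokine-derived degree of
    inflammation, and drug interventions (selective serotonin reuptake
    inhibitors, anti-inflammatory blockade, and their combination) enter as
    parameter edits. Provides an Euler-Maruyama integrator with replicate
    management, a deterministic fixed-point oracle, a condition-by-treatment
    simulation battery with tidy outputs, and comparison utilities against
    published summary values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
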