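Package: sonocryst
Title: Ultrasound-Assisted Oiling-Out Crystallization Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ultrasound-assisted anti-solvent
    crystallization of oiling-out systems. Estimates classical nucleation
    theory parameters (interfacial energy, critical radius, nucleation
    barrier, critical nucleus size) from induction-time data with a
    two-branch changepoint fit of ln(t) against 1/(ln S)^2; validates
    two-phase ternary composition measurements by mass balance and the
    lever rule; models a Gaussian-enveloped sinusoidal pulsed electric
    field used as a molecular-dynamics surrogate for an ultrasound bath;
    post-processes MD-style outputs (XVG energy tables, GRO coordinate
    frames) into pair interaction energies, axis density profiles, a
    demixing order parameter, and distance-cutoff clusters; and ships a
    seeded synthetic-data module, including a toy Brownian-dynamics
    demixing simulator, so the whole pipeline is testable without
    wet-lab or MD-engine inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
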