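Package: polypka
Title: Physics-Based pKa Prediction for Flexible Polybasic Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts microscopic and macroscopic pKa values and pH-dependent
    speciation of polyprotic molecules from per-protonation-state Gibbs free
    energies. Enumerates protonation microstates over a set of exchangeable
    sites, converts quantum-chemical free energies into microscopic pKa via a
    proton-based or water-referenced thermodynamic cycle, aggregates them into
    stepwise macroscopic pKa ladders and speciation diagrams, and fits a
    linear empirical correction against a packaged experimental benchmark of
    tetra-aza macrocycles. A site-interaction surrogate generator produces
    synthetic free-energy tables with known ground-truth pKa so the whole
    pipeline can be exercised without quantum chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
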