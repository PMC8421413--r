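Package: aaflux
Title: Kinetic and Thermodynamic Simulation of Cellular Amino Acid Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates amino acid homeostasis in mammalian cells from the
    kinetics and thermodynamics of plasma-membrane transporters. Transporters
    are described by Michaelis-Menten saturation with competition through
    apparent Km values, Hill-type saturation by coupled ions, and a
    membrane-potential factor for charged translocation complexes. Cytosolic
    concentrations are evolved under a fixed extracellular medium to a stable
    equilibrium by explicit time stepping, with optional first-order metabolic
    conversion and depletion. Includes Vmax parameterization from initial-rate
    flux or relative mRNA expression, closed-form thermodynamic accumulation
    limits for secondary active transport, in-silico transporter-knockout
    sensitivity analysis, agreement statistics against measured concentrations,
    toy model generators with analytic expectations, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
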