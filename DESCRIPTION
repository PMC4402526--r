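Package: dnapratchet
Title: Mechano-Chemical Kinetics of Processive DNA Replication Under Load
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing single-molecule optical-tweezers measurements
    of processive DNA polymerases. Implements closed-form steady-state
    velocities for three translocation-coupling schemes (dNTP-binding power
    stroke, PPi-release power stroke, and a Brownian-ratchet step between
    product release and nucleotide binding), a generic unicyclic
    master-equation solver, force-dependent Michaelis-Menten global fitting
    with bootstrap uncertainties and model discrimination, worm-like-chain
    conversion between tether length and nucleotides incorporated, a Gillespie
    simulator of replication traces with instrument noise and off-pathway
    pauses, and trace analysis (instantaneous velocities, velocity-histogram
    mixture fits, pause detection, pause-excised rates).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
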