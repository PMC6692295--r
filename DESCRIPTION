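Package: filadyn
Title: Filament Assembly, Elastic-Network Dynamics, Relaxation and
    Hydrogen-Deuterium Exchange Analysis for Helical Pilins
Version: 0.1.0
Authors@R:
    person("filadyn", "developers", email = "filadyn@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the structure and dynamics of helical
    protein filaments such as type IV pili and type 2 secretion system
    pseudopili. Builds filament models from a single protomer and helical
    rise/twist parameters, computes anisotropic network model (ANM) normal
    modes on C-alpha atoms with mode classification (bend, twist, stretch)
    and fluctuation significance tests, compares structure ensembles by
    per-residue RMSD with region detection, fits Lipari-Szabo model-free
    parameters (S2, tau_e, Rex) to 15N T1/T2/NOE data under a fully
    anisotropic rotational diffusion tensor, scores chemical shift
    perturbations, and analyses hydrogen-deuterium exchange mass
    spectrometry uptake tables with per-peptide Wald tests. A synthetic
    data module generates every input the pipeline consumes so all
    analyses are testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
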