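Package: metakin
Title: Thermodynamics and Kinetics of Ligand Deintercalation from
    Well-Tempered Metadynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of well-tempered metadynamics simulations of
    drug-DNA deintercalation over two collective variables: free-energy
    surface reconstruction from deposited Gaussian hills, standard-state
    binding Gibbs energies by Boltzmann-ratio integration with run-level
    averaging, residence-time kinetics via acceleration-factor rescaling
    with Poisson statistics, Eyring transition-state analysis and
    temperature transfer, and solvent-accessible-surface-area based
    hydrophobic energetics. Includes a 2D overdamped Langevin engine on
    analytic model landscapes that generates PLUMED-dialect HILLS and
    COLVAR inputs and exact oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
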