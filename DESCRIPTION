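Package: cdbind
Title: Geometry Descriptors and Energy Bookkeeping for Cyclodextrin
    Host-Guest Inclusion Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for cyclodextrin (CD) host-guest inclusion
    complexes. Computes per-frame geometric descriptors of guest binding
    (signed centre-of-mass distance, guest orientation, glucose tilt angles,
    cavity circularity, hydrogen-bond counts) from PDB structures and
    multi-model trajectories, classifies BS/BP/unbound binding modes, and
    turns descriptor series into occupancies, histograms, block-averaged
    uncertainties and contiguous mode intervals.  Implements the energy
    bookkeeping used in such studies: pairwise Coulomb + Lennard-Jones 12-6
    inter-fragment energy decomposition with pluggable charge sets (EDA-FF),
    omega-weighted recombination of DFT component energies into SAPT-like
    terms (sobEDAw) with the full binding-free-energy ledger, and the
    MM-PBSA decomposition ledger with additivity checks.  A synthetic
    structure and trajectory generator provides ground-truth fixtures so
    every stage is testable without a simulation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
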