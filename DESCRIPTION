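Package: LipoCG
Title: Coarse-Grained Modelling and Analysis of Bacterial Lipoprotein
    Maturation and Periplasmic Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds membrane-insertion-ready coarse-grained models of
    bacterial lipoproteins in their four maturation states (signal
    peptide, signal peptide plus diacylcysteine, diacylcysteine,
    triacylcysteine), generates Martini-style topologies for the
    lipid-modified cysteine by grafting phospholipid fragments, derives
    elastic-network restraints for folded cores, specifies membrane
    compositions and umbrella-sampling protocols, and analyses the
    resulting ensembles: residue-lipid contact fingerprints, replicate
    reproducibility, membrane deformation surfaces, WHAM free-energy
    profiles with Bayesian-bootstrap errors, and the thermodynamic cycle
    of lipoprotein transfer through the Lol pathway. The molecular
    dynamics engine itself is external; this package prepares its inputs
    and interprets its outputs, and ships synthetic-data generators with
    known ground truth so every analysis is testable without simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
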