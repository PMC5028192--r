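Package: rnavoid
Title: Avoidance of Stochastic mRNA:ncRNA Interactions in Prokaryotes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the depletion ("avoidance") of stable stochastic
    intermolecular interactions between mRNA 5' regions and abundant
    non-coding RNAs in bacterial and archaeal genomes. Provides a simplified
    nearest-neighbour thermodynamic engine for intramolecular folding,
    intermolecular hybridisation and accessibility-corrected interaction
    energies; an exact dinucleotide-preserving shuffle null model; per-genome
    extrinsic (energy-shift) and intrinsic (G+C separation) avoidance tests;
    positional avoidance profiles along ncRNAs and mRNAs with structural
    accessibility association; relates avoidance, codon adaptation and 5' end
    structure to protein abundance; and designs synonymous coding sequences
    with controlled avoidance under G+C constraints. Ships seeded synthetic
    data generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
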