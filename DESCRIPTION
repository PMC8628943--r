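Package: isoxlink
Title: Identification of Transglutaminase Isopeptide Cross-Linked Peptides
    from Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("isoxlink", "developers", email = "isoxlink@example.org",
           role = c("aut", "cre"))
Description: A search engine for transglutaminase (TG) Lys-Gln isopeptide
    cross-linked peptide pairs in tandem-MS data of protease-digested
    proteins. Implements isopeptide mass arithmetic (loss of NH3 on
    condensation of the lysine epsilon-amine with the glutamine amide),
    in silico tryptic digestion with missed cleavages, enumeration of
    cross-linkable candidate pairs with variable-modification expansion,
    branched b/y fragment prediction for collision-induced dissociation,
    tolerance-based peak matching with a four-score match statistic family
    (score, pp, pp2, pp_tag) and a per-site overall score, reversed-sequence
    target-decoy false discovery rate estimation, FASTA/MGF/TSV input and
    output, a seeded synthetic CID spectrum generator for benchmarking, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
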