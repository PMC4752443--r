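Package: radscan
Title: Clade-Wide Scans of Introgression, Lineage-Specific Substitution,
    and Environmental Association in Rapid Radiations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phylogenomic analysis of the three sources of adaptive
    variation in a rapidly radiating species group: cross-species
    introgression (windowed ABBA-BABA D-statistics with block bootstrap,
    five-taxon D_FOIL direction tests, and gene-tree topology counting),
    lineage-specific de novo protein-coding substitutions (unambiguous
    clade-diagnostic substitution counting with representative-sequence
    and monophyly eligibility rules), and environment-driven sorting of
    ancestral variation (a "PhyloGWAS" perfect-association scan with a
    multispecies-coalescent null).  Includes a structured-coalescent
    simulator of diploid multisample variant matrices over a labeled
    species tree, with introgression pulses and injected
    environment-sorted alleles, used for truth-table recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    seqinr,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
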