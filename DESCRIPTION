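Package: mrakit
Title: Design and Validation Toolkit for Multiplex Restriction Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating Multiplex Restriction Amplicon
    Sequencing (MRASeq) genotyping panels from a reference genome. Mines all
    amplicon targets delimited by a pair of restriction sites (PstI/MspI by
    default), summarizes their spacing, density and length spectrum, ranks
    restriction-anchored specific primer pairs under nearest-neighbour melting
    temperature constraints, designs IUPAC degenerate primers with degeneracy
    accounting, assembles two-step-PCR fusion primers, predicts amplification
    in silico, and simulates barcoded variable-length amplicon reads. Also
    provides the read preprocessing (tail/spacer excision, poly-A padding)
    needed to feed reads into GBS-style SNP callers, and call-rate/allele
    frequency/heterozygosity filters for the resulting genotype matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
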