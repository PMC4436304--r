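Package: gofamcat
Title: Cataloguing Transcription-Factor Gene Families and Homoeolog
    Evolution in Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for genome-wide cataloguing of transcription-factor
    gene families (built around the basic/helix-loop-helix, bHLH, domain)
    across multiple annotated sequence sources, and for analysing the fate
    of homoeologous gene copies in allopolyploids.  Candidate proteins are
    found by local alignment against a probe set of representative domains,
    validated against a consensus profile (sub-region presence and
    consensus-residue fraction), collapsed into a coded reference gene set
    by guide-tree branch-length thresholds, and classified into subfamilies
    by a multi-method phylogenetic support rule (neighbour joining with
    bootstrap, maximum parsimony, and Poisson-model maximum likelihood).
    Homoeologous gene pairs are compared for genome origin, exon-intron
    structure, in-frame indels, simple-sequence-repeat tract lengths, and
    LTR-retrotransposon insertions; relative transcript levels are computed
    from qRT-PCR Ct tables with dual reference genes.  A synthetic-family
    generator with planted ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
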