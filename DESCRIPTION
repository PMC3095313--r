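Package: divclock
Title: Codon-Level Divergence, Molecular-Clock Dating and In-Silico Locus
    Characterization for Recent Gene Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse recently duplicated plant genes from pairwise
    sequence comparisons: Nei-Gojobori (1986) synonymous/nonsynonymous
    divergence with Jukes-Cantor correction, Jukes-Cantor distances for
    non-coding regions, molecular-clock rescaling of divergences into split
    and duplication ages from calibration anchors, neighbor-joining trees
    with codon-aware bootstrap and a Bayes-factor topology decision rule,
    and in-silico locus characterization (restriction digests with Southern
    probe fragment prediction, exon/intron gene models with intron-retention
    transcript variants, protein molecular weight and isoelectric point).
    Includes seeded simulators for codon pairs, non-coding pairs, multi-locus
    clock datasets and two-paralog loci so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    knitr,
    optparse,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
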