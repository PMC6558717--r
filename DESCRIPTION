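Package: bbxkit
Title: Comparative Analysis of Plant B-BOX Zinc-Finger Gene Families
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for comparative analysis of the B-BOX (BBX)
    zinc-finger transcription-factor family in plant genomes, modeled on the
    two epiphytic orchids Dendrobium officinale and Phalaenopsis equestris.
    Detects B-BOX1, B-BOX2 and CCT domains by consensus-pattern scanning and
    assigns domain architectures and clades (I-V); finds ortholog and paralog
    pairs by reciprocal best hits over global protein alignments; estimates
    Ka and Ks by the Nei-Gojobori (1986) counting method with Jukes-Cantor
    correction, including 150 bp / 9 bp sliding-window selection scans;
    reconstructs domain-architecture evolution on neighbor-joining trees with
    Fitch parsimony; scans 1500 bp promoters for named plant cis-regulatory
    elements; and quantifies expression from FPKM matrices and qRT-PCR Ct
    tables (2^-ddCt). Seeded synthetic-genome generators emulate every input
    with recorded ground truth so the whole pipeline can be exercised and
    validated without genome downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    withr
Config/testthat/edition: 3
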