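Package: allelome
Title: Allele-Aware Analyses for Haplotype-Resolved Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, self-contained pipeline for allele-level analyses in
    haplotype-resolved diploid genomes: allele-pair identification by
    collinear-block chaining between homologous chromosomes, per-tissue
    allelic expression-bias testing and four-level bias classification,
    dynamic/stable allele ranking, codon-aware Ka/Ks estimation (NG86 with
    Jukes-Cantor correction), promoter PWM scanning with exact p-values and
    shared/specific TFBS accounting, nearest-transposable-element distances,
    weighted coexpression network module detection with an
    eigengene-distance allele-divergence rule, Ks-peak WGD dating,
    LTR-retrotransposon lifecycle classification and removal-rate
    statistics, and k-mer genome-size estimation. A seeded synthetic-data
    generator emulates every input with planted ground truth so the whole
    pipeline is testable end to end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
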