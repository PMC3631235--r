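Package: pmindex
Title: Pre-mRNA Decay Index Analysis for Yeast Intron-Containing Genes
Version: 0.1.0
Authors@R:
    person("pmindex", "maintainers", email = "pmindex@example.org",
           role = c("aut", "cre"))
Description: Quantifies stress-induced changes in pre-mRNA levels of
    Saccharomyces cerevisiae intron-containing genes. Computes the PM
    index (PMi), a log2 ratio-of-ratios of intron versus exon signal
    between stressed and unstressed cells, from tiling-array probe
    intensities and from efficiency-corrected qPCR delta-delta-Ct data.
    Includes probe-to-feature assignment, median summarization,
    transcription-rate time-course normalization and K-means clustering,
    PMi-versus-delta-TR regression, hypergeometric gene-set enrichment,
    and a kinetic synthetic-data generator (transcription, splicing,
    pre-mRNA and mature-mRNA decay) with genotype-dependent stress
    responses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
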