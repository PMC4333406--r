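Package: hzascreen
Title: Genome-Wide Screening for Paired HZA and GATA Enhancer Elements
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and genome-wide screening of the high zinc activation
    (HZA) enhancer element and its partner intestinal GATA element in
    nematode promoters. Provides deterministic EM motif elicitation on
    small promoter sets, position weight matrix construction with exact
    dynamic-programming null score distributions and p-value cutoffs,
    both-strand scanning of upstream intergenic regions in the
    translation-start coordinate convention, detection of HZA+GATA element
    pairs under spacing, orientation, cis-regulatory-module and distance
    criteria, pairwise-alignment-based conservation checks, and a seeded
    synthetic-genome generator with planted modules for ground-truthed
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
biocViews: MotifDiscovery, SequenceMatching, GenomeAnnotation, Transcription
Config/testthat/edition: 3
RoxygenNote: 7.3.3
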