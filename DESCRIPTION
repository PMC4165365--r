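Package: circkit
Title: Annotation-Free Discovery and Characterization of Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects back-spliced junctions from RNA-seq reads by exact two-part
    split alignment with GT-AG splice-signal refinement, quantifies the circular
    fraction of each junction from donor/acceptor/junction probe counts, filters
    junctions into a high-confidence circular RNA catalog, and characterizes
    candidates: trans-splicing discrimination and intron retention from mate
    reads, poly(A)-selection comparison, abundance inference from gene FPKM,
    Jensen-Shannon cell-type specificity against expression-matched linear
    controls, cross-species ortholog overlap and codon-position conservation
    tests, ribosome-footprint translation assessment, and microRNA seed-site
    counting with composition-preserving permutation nulls. Includes a synthetic
    data generator that emits genomes, spliced linear and circular transcripts
    at known circular fractions, paired-end fragments and ribosome-protected
    fragment reads, together with the ground truth needed for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stringi,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
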