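Package: mipronet
Title: MicroRNA Promoter Discovery and TF-miRNA Network Motifs from RNA
    Polymerase II and Transcription Factor ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs microRNA-mediated regulatory networks from
    genome-wide RNA polymerase II and transcription-factor binding data.
    Fits a five-parameter Poisson shape model of RPol II occupancy around
    transcription start sites by maximum likelihood, scans upstream regions
    of intergenic microRNAs for TSS-like binding patterns and calls promoter
    regions at a target empirical false discovery rate, identifies
    collaborating transcription factors by position-specific score matrix
    enrichment with a density-ratio FDR cutoff rule, computes
    interval-overlap permutation and binomial co-occurrence statistics,
    CpG-island and TSS-distance profiles, finds seed-match microRNA target
    sites (8mer, 7mer-m8, 7mer-1A), and assembles feedback and feed-forward
    network motifs. Includes a fully seeded synthetic-data generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
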