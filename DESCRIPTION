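Package: tusmarkers
Title: Transcriptome Marker Discovery and Tag-Based Expression Analysis
    from EST Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis of EST/short-transcript-read
    assemblies built from tentative unique sequences (TUSs): poly-A
    trimming and low-complexity screening, classification of two-read
    flat-coverage contigs as high-confidence singletons, MISA-style
    simple sequence repeat (SSR) mining with compound-repeat merging and
    Class-I selection, 36-bp tag mapping with per-million normalization
    and R-statistic differential expression calls, inter-genotype SNP
    detection with allele-frequency/read-depth classification and
    confidence tiers, intron-spanning (ISR) and conserved-ortholog (COS)
    marker design from spliced alignments and cross-species similarity
    cascades, and a fully seeded synthetic-data generator with planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    BiocGenerics,
    VariantAnnotation,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
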