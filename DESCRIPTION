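Package: buttseq
Title: Nascent RNA 3'-End Profiling: Pause-Site Detection, Pausing
    Indices, and Circadian Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of nascent-RNA 3'-end sequencing
    (Butt-seq style) data. Converts aligned paired-end reads to
    single-nucleotide RNA polymerase positions (UMI deduplication,
    soft-clip handling, contaminant masking), calls promoter-proximal
    pause sites against a bootstrap multinomial null, computes
    pause-anchored and fixed-window pausing indices with ECDF/KS
    comparison, median-of-ratios normalization, metagene profiles with
    bootstrap confidence bands, subnucleosomal MNase dyad analysis with
    pause-distance clustering, two-tissue pause/elongation concordance,
    and circadian exon-only time-course quantification. Includes a
    ground-truthed synthetic-data generator emulating the statistical
    structure of such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
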