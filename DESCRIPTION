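Package: nucshift
Title: Nucleosome Repositioning Analysis for Two-Channel Promoter Tiling
    Microarrays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects drug-induced nucleosome repositioning at promoters from
    two-channel tiling microarrays that compare mononucleosomally-protected
    DNA (Cy3) against bare genomic DNA (Cy5) over 2-kb windows centered on
    transcription start sites. Provides the tiling probe-layout model, a
    synthetic-data generator with known nucleosome-map truth and injected
    repositioning events (eviction, gain, shift), per-array normalization and
    log2-ratio occupancy profiles, Pearson-correlation change calls with the
    all-replicate-pair intersection rule (r < 0.7), time-course and drug set
    partitions, a sequence-directed nucleosome occupancy score with
    DNA-directed versus DNA-independent classification, occupancy-state
    annotation of TSS and transcription-factor binding sites, and Fisher
    exact gene-set enrichment with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
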