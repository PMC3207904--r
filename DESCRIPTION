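Package: episwitch
Title: Coordinated Histone-Mark Switching Analysis Around Transcription
    Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: TSS-anchored analysis of ChIP-seq histone-mark data for
    studies of coordinated epigenomic switching, as in oncogene-induced
    senescence. Quantifies per-gene promoter mark levels as the maximum
    sliding-window reads-per-million statistic around the transcription
    start site, classifies genes into mark-positive/negative states with
    hard thresholds, calls between-condition transitions and the
    coordinated switch categories (K27-to-K4, bivalent-to-K4, K4-to-K27,
    de-novo K27), ranks genes by expression fold change and tests
    categories for rank enrichment with a Kolmogorov-Smirnov statistic,
    calls transcription-factor binding sites against a Poisson background
    and assigns them to genes by distance, screens MeDIP promoter
    methylation for between-condition changes, and simulates complete
    synthetic input bundles with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
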