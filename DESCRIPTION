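Package: poolscape
Title: Pool-Seq Landscape Genomics of Adaptation to Metalliferous Soils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a Pool-seq landscape-genomics
    workflow for detecting genes and pathways involved in adaptation to
    metalliferous (trace-metal-enriched) soils. Provides variant filtering of
    pooled variant calls, pooled allele-frequency estimation, latent-factor
    environmental association with genomic-control (lambda) calibration and
    false-discovery-rate control, covariance-corrected cross-validation of
    association hits, per-gene diversity statistics (segregating sites, pi,
    Watterson's theta, Tajima's D) with genome-wide percentiles, polygenic
    max-|z| gene-set enrichment with pruning, a candidate-gene cascade with
    variant-effect classification, and a synthetic-data generator that
    emulates the statistical structure of multi-population Pool-seq designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    MASS,
    lmtest,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite
Config/testthat/edition: 3
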