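Package: combichip
Title: Combinatorial Transcription Factor Occupancy Analysis for Promoter
    ChIP-chip Data
Version: 0.1.0
Authors@R:
    person("Combichip", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Threshold-based analysis of promoter-array (ChIP-chip)
    enrichment tracks during keratinocyte differentiation: promoter
    filtering, per-promoter mean enrichment and binding calls for CREB,
    C/EBP and c-Jun family factors, differential RNA polymerase II /
    H3K9ac / mRNA calls, classification of promoters into the 2^3
    co-occupancy patterns, chi-square enrichment of induced and repressed
    promoters per pattern, methylation-stratified analyses, consensus and
    composite DNA-motif scanning with combination enrichment, and a
    truth-tagged synthetic data generator that emulates the array design
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
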