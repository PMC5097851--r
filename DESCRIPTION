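Package: epimapred
Title: Gene Expression Modelling from TSS-Proximal ChIP-Seq Signal via
    MapReduce Primitives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes gene-level epigenetic scores from histone-modification
    or transcription-factor ChIP-seq signal aggregated around transcription
    start sites, and fits L2-regularised linear models of mRNA abundance in
    which the large matrix products are expressed as deterministic
    map-shuffle-reduce programs. Includes a minimal MapReduce engine,
    readers and writers for UCSC wiggle, BED6 and expression/score tables,
    ridge regression with one-standard-error ten-fold cross-validated
    lambda selection, directed cross-cell-line evaluation, hierarchical
    clustering of expression residuals, and a seeded synthetic-data
    generator producing WIG/BED/TSV fixture suites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    rtracklayer,
    optparse
Config/testthat/edition: 3
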