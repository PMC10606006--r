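Package: sgitrare
Title: Multi-Trait Rare-Variant Gene-Based Association via a Shared
    Genetic Impact Trait
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene-based rare-variant association analysis of several
    genetically correlated binary traits from summary statistics.
    Builds a shared genetic impact trait (SGIT) as the
    heritability-maximizing linear combination of the original traits,
    computes covariate-adjusted logistic score-test summary statistics
    (exome-wide association scan), collapses ultra-rare variants by
    minor allele count, and tests genes under nested functional
    annotation masks with burden, SKAT, SKAT-O, a principal-component
    test, and the aggregated Cauchy omnibus (ACAT-O).  Approximate
    conditional analysis removes association signals located outside a
    gene using linkage-disequilibrium information, in the manner of
    conditional-and-joint (COJO) analysis.  A liability-threshold
    synthetic cohort generator with a shared-factor genetic
    architecture supports calibration, parameter-recovery, and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
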