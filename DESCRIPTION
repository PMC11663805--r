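Package: cdrscan
Title: Detection of Centromere Dip Regions from Long-Read CpG Methylation Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects centromere dip regions (CDRs) - localized windows of CpG
    hypomethylation inside otherwise hypermethylated alpha-satellite
    higher-order-repeat arrays - from per-CpG methylation pileups in bedMethyl
    format. Bins the methylation signal over target regions, restricts it to
    alpha-satellite ("ALR/Alpha") annotated bins, selects candidate dips by
    median-relative depth, filters them by topographic prominence, extends
    call boundaries by a mean-minus-SD rule, and writes BED calls plus a
    multi-track diagnostic plot. Includes a seeded synthetic-data generator
    of centromeric methylation fixtures and a precision/recall evaluation
    harness against planted truth intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
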