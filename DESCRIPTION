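Package: mendeviate
Title: Mendelian Deviations and Germline Mutation Frequency in SNP-Array Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Mendelian deviations (candidate de novo point mutations)
    in parent-offspring trio SNP-array genotypes, infers the parent of origin
    of each deviation by Mendelian transmission logic with confidence- and
    nearest-marker-based deductions for ambiguous sites, classifies the six
    pyrimidine-standardized substitution classes with CpG-island flagging,
    and estimates the per-trio germline mutation frequency MF_MD together
    with the group-level statistics used in radiation-exposure cohort
    studies (equal-variance t-test, variance-ratio F-test, dose-response
    regression, parent-of-origin subgroup and parental-age analyses). A
    Hardy-Weinberg trio simulator with injected de novo mutations,
    genotyping error, and no-calls supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
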