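Package: qmspr
Title: Relative Methylation Quantification of Repetitive Elements by
    Bisulfite qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative methylation-specific PCR (qMSP) analysis
    of repetitive elements such as LINE-1 and Alu: standard-curve calibration
    with amplification-efficiency and CT-cutoff estimation, selection between
    the Livak (delta-delta-CT) and efficiency-corrected Pfaffl quantification
    formulas, calibrator-normalized relative methylation levels with
    replicate aggregation and exclusion rules, PCR-amplification-bias
    assessment on defined-methylation mixture panels, and group-level
    statistics with a normality-gated test choice. Includes a mechanistic
    simulator of bisulfite-converted two-allele qPCR reactions so that every
    stage of the pipeline can be validated without wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
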