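Package: ctdnatrack
Title: Longitudinal ctDNA Monitoring with Mean VAF and t-MAD Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circulating tumor DNA (ctDNA) in serial plasma samples
    from two complementary assays: per-sample mean variant allele frequency
    (VAF) from targeted panel sequencing, and the t-MAD copy-number
    instability score from shallow whole-genome sequencing. Between-visit
    changes in both metrics are scored against decision thresholds derived by
    ROC/Youden analysis of progression labels, early molecular progression is
    called at radiographically stable time points and validated by a
    sustained-increase rule, and lead times versus radiographic progression
    are assigned per therapy line. Includes survival stratification by
    baseline ctDNA detectability and a seeded synthetic-cohort generator that
    emulates the longitudinal study design with ground truth for recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
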