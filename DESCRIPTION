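Package: ecsubtype
Title: One-Step NGS Molecular Subtyping of Endometrial Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchical molecular classification of endometrial carcinoma
    from a single targeted NGS panel: samples are assigned to the POLE
    (ultramutated), MSI-H (hypermutated), copy-number high (CNH) or
    copy-number low (CNL) prognostic group from pathogenic POLE variants,
    tumor mutational burden, microsatellite read-length histograms and
    copy-number segments. Includes cohort summarization against
    clinicopathological strata, Kaplan-Meier / log-rank / Cox survival
    stratification, classifier concordance statistics (overall accuracy and
    Cohen's kappa with bootstrap confidence intervals), ARID1A/ZFHX4
    biomarker sub-stratification of CNL/MSI-H tumors, and a seeded synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
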