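Package: mrpanel
Title: Two-Sample Mendelian Randomization Across Exposure Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) on GWAS summary
    statistics, built for many-exposure panels such as genus-level gut
    microbiota screens against a binary disease outcome. Provides dialect-aware
    readers for summary-statistics tables, instrument selection (locus-wide
    p-value threshold, greedy LD clumping, minor-allele-frequency filter),
    allele harmonization with frequency-based palindrome resolution, a
    seven-estimator causal-effect ensemble (inverse-variance weighted, maximum
    likelihood, MR-Egger, weighted median, weighted mode, MR-PRESSO, and
    constrained maximum likelihood with BIC model averaging), Cochran's Q and
    leave-one-out diagnostics, instrument-strength F statistics and power
    approximations, Storey q-value false discovery rate control with
    significant/suggestive classification, bidirectional panel analysis, and a
    seeded synthetic summary-statistics generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
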