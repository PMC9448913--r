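Package: dyadDMR
Title: Joint Mother-Child Differentially Methylated Region Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of differentially methylated regions (DMRs) in paired
    mother-child methylation-array cohorts. Implements array-style
    preprocessing (beta values from methylated/unmethylated intensities,
    detection p-value filters, contaminant probe removal), a bump-hunting
    DMR engine (CpG clustering, covariate-adjusted per-probe linear models,
    cluster-wise local-regression smoothing, area statistics with a residual
    bootstrap null), joint two-cohort significance via z-statistic
    correlation and intersection at a squared significance level, adversity
    covariate association, cohort comparison statistics from summary data,
    and a synthetic EPIC-like data generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
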