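Package: transcortex
Title: Transcriptome-Neuroimaging Association Analysis for Case-Control Brain Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links cortical gene expression to case-control neuroimaging
    abnormality maps. Computes regional case-control effect sizes (Cohen's d)
    for gray matter volume and resting-state functional measures (ALFF, fALFF,
    ReHo), summarises effect maps and regional expression by their first
    principal components, screens every gene's spatial expression profile
    against a target map with Spearman correlation and Bonferroni selection,
    relates transcriptional correlates to postmortem differential gene
    expression through a bin-based correlation estimator, and tests gene-set
    over-representation with Fisher's exact test. Includes a probe-to-region
    expression atlas builder (background filtering, differential-stability
    probe selection, within-donor normalisation and aggregation) and a
    synthetic-data generator with planted ground truth so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
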