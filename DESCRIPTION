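Package: ewasdmr
Title: Longitudinal EWAS Mixed Models, Spatially Combined DMRs, and
    Region-Level eQTM/metQTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal epigenome-wide association analysis of
    two-visit methylation cohorts with several progression phenotypes.
    Per-CpG linear mixed models test whether the pre- to post-visit change
    in DNA methylation (the phenotype-by-visit interaction) or the average
    methylation level (the phenotype main effect) differs across groups.
    Probe-level p-values are combined spatially with a from-scratch
    comb-p-style pipeline (distance-binned autocorrelation, Stouffer-Liptak
    combination, sliding-window peak finding, Sidak region correction), and
    candidate regions are retained under direction-consistency rules.
    Retained regions are summarised per subject by a first principal
    component and correlated with gene expression (eQTM, Spearman) and
    metabolite levels (metQTM, standardized betas with Box-Cox
    pre-transform). A synthetic cohort generator with planted region
    effects and linked omics makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
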