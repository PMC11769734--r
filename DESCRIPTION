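Package: pairedmrmc
Title: Paired Split-Plot Multireader Multicase Noninferiority Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for paired, split-plot, multireader
    multicase (MRMC) observer studies comparing two diagnostic modalities,
    as used to assess noninferiority of biparametric versus multiparametric
    prostate MRI for clinically significant prostate cancer. Provides
    long-format reader-study data handling and validation, per-reader
    empirical AUROC and sensitivity/specificity under configurable
    PI-RADS positivity rules, Obuchowski-Rockette analysis of variance with
    jackknife covariance components adapted to split-plot block structure,
    Wald noninferiority tests with Holm-Bonferroni and hierarchical
    gatekeeping multiplicity control, decision curve analysis (net benefit
    and net reduction in interventions), and a Roe-Metz-style
    latent-variable simulator that generates paired split-plot reader
    studies calibrated to published marginal characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
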