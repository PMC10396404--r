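Package: mdagplan
Title: Analysis Planning for Multivariable Missing Data Using Missingness DAGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and executing analyses with missing data in
    multiple variables using missingness directed acyclic graphs (m-DAGs).
    Represents missingness assumptions as an m-DAG, checks the graph against
    the overarching assumptions of the canonical point-exposure catalogue,
    determines recoverability of a target estimand (marginal mean or
    regression-adjusted exposure effect) by canonical classification and by a
    graphical complete-records-validity criterion, recommends an analysis
    (complete-records analysis, multiple imputation, or delta-adjusted
    multiple imputation), and executes it via a built-in fully conditional
    specification imputation engine with pattern-mixture delta adjustment and
    Rubin's-rules pooling. A structural-equation simulator with calibrated
    logistic missingness mechanisms and a Monte Carlo harness verify every
    graphical verdict empirically.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
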