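Package: dxeval
Title: Diagnostic Test Performance Evaluation with Confidence Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates binary and quantitative diagnostic tests against a
    binary reference standard. Computes sensitivity, specificity, accuracy,
    predictive values at a user-supplied population prevalence, likelihood
    ratios, and the Youden index, each with a 95% confidence interval
    (Wilson score intervals for proportions, log-scale intervals for
    likelihood ratios, bound-propagation for predictive values, and a
    binomial-variance interval for the Youden index). For quantitative
    tests it builds the full ROC curve, estimates the AUC with a DeLong
    confidence interval, selects the closest-to-top-left optimal cutoff,
    and draws a stratified-bootstrap sensitivity band. Includes spreadsheet
    input/output with strict validation, a synthetic-data generator for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    readxl,
    zip,
    ggplot2,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
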