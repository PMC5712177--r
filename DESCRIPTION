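Package: lognsize
Title: Sample Size for Two-Group Comparisons of Log-Normal Outcomes
    Specified by Medians
Version: 1.0.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Sample size calculation for two-group comparisons of positively
    skewed outcomes analysed by a two-sample t-test on the log scale, where
    the clinically important difference is specified as a difference in
    medians on the untransformed scale and variability as untransformed
    standard deviations.  Assuming log-normal outcomes, group medians and raw
    standard deviations are converted to log-scale means and variances in
    closed form and fed into the standard normal-approximation sample size
    formula.  Includes a corrected formula for exponentially distributed
    outcomes, design-effect inflation for clustered designs, a Monte-Carlo
    engine estimating the power of the log-scale t-test, the Mann-Whitney U
    test and the raw-scale t-test for log-normal and exponential data, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
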