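Package: cuedenum
Title: Simulation and Bayesian Central-Tendency Analysis of Cued Number-Line Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying how visual attention shapes numerosity estimation
    on a number line. Simulates Posner/Egly cue-validity enumeration experiments
    (valid same-location, invalid same-object and invalid different-object trials)
    with a Bayesian central-tendency observer, generates non-overlapping dot-array
    stimuli, applies the standard preprocessing rules (training-trial exclusion,
    per-condition 2-SD outlier removal, reaction-time floor), fits responses by
    maximum likelihood under scalar variability and by power functions, fits the
    width of the central prior to number-line data, and reproduces the predicted
    relationship between internal noise and compressive non-linearity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
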