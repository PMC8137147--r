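Package: wheeltask
Title: Simulation and Cross-Laboratory Analysis of a Standardized Visual
    Two-Alternative Forced-Choice Wheel Task
Version: 0.1.0
Authors@R:
    person("Mouse", "Behavior Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative simulator and analysis pipeline for a standardized
    head-fixed mouse decision-making task in which animals report the side of
    a visual grating by turning a wheel. Implements the trial-by-trial task
    protocol (staged contrast introduction, debiasing repeat trials,
    truncated-geometric bias blocks), a trial-history logistic choice model,
    four-parameter erf psychometric fitting, automated training-proficiency
    criteria, and a cross-laboratory reproducibility assessment based on
    leave-one-out lab-membership classification against a shuffle null.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    survival,
    truncnorm,
    utils
LinkingTo: Rcpp
Suggests:
    numDeriv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
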