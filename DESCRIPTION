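Package: kinemorph
Title: Landmark Motion Morphing and Reverse-Rating Analysis for Gesture Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for working with 2D landmark trajectories of gesturing
    stick figures: standardization to a common body height and screen anchor,
    vertical and horizontal expansiveness scoring with maximal-window
    selection of prototype sequences, axis-isolated motion prototypes and
    slider-controlled morphing between a prototype and a neutral standard
    posture (amplitude weights plus a velocity-to-frame-rate mapping), a
    headless implementation of the reverse-rating adjustment protocol with
    simulated participants, and a relative-importance-weights logistic
    regression pipeline (descriptive quartiles, multi- and single-predictor
    models with profile-likelihood confidence intervals, Bonferroni
    correction, and confidence-interval overlap heuristics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
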