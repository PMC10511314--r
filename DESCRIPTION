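Package: coda24
Title: Compositional Analysis of 24-Hour Movement Behaviors and Obesity Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how changes in the composition of 24-hour
    movement behaviors (sleep, sedentary behavior, light physical activity,
    and moderate-to-vigorous physical activity) relate to concurrent changes
    in obesity indicators such as body mass index and waist circumference.
    Provides Aitchison-geometry primitives for 4-part daily time-use
    compositions (closure, perturbation, compositional means, centred and
    isometric log-ratio pivot coordinates), valid-day filtering and cohort
    descriptives for accelerometer-derived participant tables,
    change-on-change linear regression fitted in every behavior-first pivot
    parameterization, compositional isotemporal substitution predictions
    with delta-method confidence intervals, a logistic-normal synthetic
    cohort generator, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
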