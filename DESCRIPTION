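Package: jitaema
Title: Just-in-Time Adaptive Ecological Momentary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A measurement toolkit for just-in-time adaptive ecological
    momentary assessment (JITA-EMA): a graded-response-model computerized
    adaptive testing engine with classification-oriented stopping rules and
    dynamically tailored (cosinor-based) classification cutoffs, together
    with a synthetic EMA study simulator and an evaluator that computes
    sensitivity, specificity, and kappa for momentary-state classification
    under clustering. Includes item-bank generation and I/O, maximum a
    posteriori scoring, maximum-expected-information item selection,
    diurnal-rhythm (cosinor) regression, random-intercept logistic
    evaluation by Gauss-Hermite quadrature, and a small command-line
    surface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
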