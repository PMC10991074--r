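Package: mistkit
Title: Misinformation Susceptibility Testing and Scale-Development Toolkit
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for administering and developing the Misinformation
    Susceptibility Test (MIST) and for Verification-done scoring of balanced
    true/false news-headline tests. Ships the published MIST-20, MIST-8 and
    MIST-16 item banks with their 3PL parameters and US/UK population norms,
    scores binary responses into veracity discernment (V), real-news (r) and
    fake-news (f) detection and the distrust (d) and naivete (n) response
    biases, and provides the scale-development machinery used to build such
    tests: tetrachoric correlations, parallel analysis, exploratory factor
    analysis, reliability (alpha, two-factor McDonald's omega),
    three-parameter-logistic IRT calibration with EAP scoring and DIF
    screening, an EFA/IRT item-selection decision tree, exploratory graph
    analysis (EBICglasso + Walktrap, network loadings, unique variable
    analysis, bootstrap stability, TEFI), a synthetic-respondent simulator,
    and pre/post intervention evaluation with power utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
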