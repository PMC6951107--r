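Package: loopdep
Title: Retrieval Dependency and Independent-Forgetting Models for
    Three-Element Episodic Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying whether complex episodic events are forgotten
    holistically or element by element. Implements the retrieval-dependency
    statistic for cued-recognition data on location-person-object triplets
    (six 2x2 contingency tables of joint retrieval, compared against an
    independence model built from marginal accuracies), a Monte-Carlo model
    of independent forgetting that degrades immediate-test response matrices
    to delayed-test accuracy, generators for the encoding and test trial
    schedules of the underlying experimental designs (closed- and open-loop
    associative structures, six-alternative forced choice), a synthetic
    cohort simulator with explicit holistic versus independent encoding and
    all-or-none versus association-independent forgetting regimes, and the
    inferential layer applied to dependency scores: one-sample t tests,
    pooled Cohen's d, JZS Bayes factors with Cauchy priors, and a-priori
    power analysis via the noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
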