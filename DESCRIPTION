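Package: gafs8
Title: Graded Response Model Tools for the General Alexithymia Factor Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Item response theory machinery for norm-referenced scoring of the
    8-item general alexithymia factor score (GAFS-8) derived from TAS-20 item
    responses. Implements the logistic graded response model (category trace
    lines, information functions, expected scores), maximum a posteriori and
    expected a posteriori latent trait scoring against an embedded published
    calibration, Bock-Aitkin EM estimation of single- and multi-group graded
    response models with Oakes-identity standard errors and limited-information
    fit statistics, iterative Wald differential item functioning tests with
    wABC/ESSD/ETSSD/UETSDS effect sizes, model-based bifactor indices
    (categorical omega coefficients, explained common variance, percentage of
    uncontaminated correlations), robust Bayesian correlation and t-test
    estimators with region-of-practical-equivalence Bayes factors, readability
    formulas (FORCAST, Flesch-Kincaid), a synthetic two-group response
    generator, and an empirically driven item-reduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
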