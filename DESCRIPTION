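Package: growthrn
Title: Reaction-Norm Models of Daily Plant Growth for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates genotype- and growth-stage-specific reaction norms of
    daily plant growth to soil moisture from time-series field phenotypes, and
    predicts whole-season growth trajectories of untested genotypes and
    environments. Implements per-day bias correction of remote-sensed canopy
    height against manual ground truth, smoothing-spline growth-curve
    interpolation, separable spatio-temporal Gaussian-kernel interpolation of
    sparse soil-moisture measurements with leave-one-out bandwidth selection,
    linear (VanRaden) and Gaussian genomic relationship matrices, a
    varying-coefficient B-spline model of daily growth fitted by locally
    weighted least squares, a random-forest daily-growth model, GBLUP
    benchmarks solved by REML, three cross-validation schemes (among
    genotypes, among environments, and both), and a synthetic field-trial
    simulator with known ground-truth reaction norms for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    ranger,
    jsonlite,
    yaml
Suggests:
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
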