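Package: selfarray
Title: Progeny-Array Selfing-Rate Estimation from Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating individual selfing rates in hermaphroditic
    animals from progeny arrays of multilocus microsatellite genotypes.
    Implements exclusion-based Mendelian paternity assignment (juvenile
    inclusion filtering, maternal comparison, candidate-father mismatch
    scoring), per-family selfing-rate estimation with proportion confidence
    intervals, classification of selfing propensity (outcrosser, plastic
    switcher, plastic mixer, selfer, and the apparent categories inferred
    without genotypes), contingency-table statistics for mating-trial
    treatment effects, Weir-Cockerham inbreeding coefficients, and a forward
    simulator of a paired-mating-trial experiment (founder genotypes,
    allosperm-sired broods, inbreeding depression, allelic dropout and null
    alleles) that provides truth-labelled data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
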