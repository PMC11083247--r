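Package: waxnose
Title: Odor Grading of Food-Grade Paraffin Wax from HS-GC/MS Total Ion Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Treats a headspace GC/MS instrument as a mass-spectrometry-based
    electronic nose for grading the odor intensity of food-grade paraffin wax.
    Chromatographic runs are collapsed into base-peak-normalized total ion
    spectra (TIS, m/z 50-550), headspace generation conditions are optimized
    with a Box-Behnken design and response-surface methodology (pure-error
    ANOVA, lack-of-fit test, constrained surface maximization), and odor grade
    is classified and quantified with hierarchical clustering, PCA, Gaussian
    support vector machines, random forests with permutation-importance
    reduction, partial least squares regression, and support vector regression.
    A synthetic GC/MS run generator with grade-dependent marker ions stands in
    for the instrument so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    kernlab,
    randomForest,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mzR,
    mixOmics,
    withr,
    optparse
Config/testthat/edition: 3
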