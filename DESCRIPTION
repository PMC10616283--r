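Package: drgrade
Title: Diabetic Retinopathy Severity Grading from Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for five-grade diabetic
    retinopathy severity classification from retinal fundus images.
    Segments five retinal structures (optic disc, macula, blood vessels,
    exudates, hemorrhages) by fraction-of-range intensity thresholding with
    disc-structuring-element morphology, extracts a multidomain Diabetic
    Retinopathy Feature Vector (Fourier, cosine, Gabor, Haar-pair wavelet and
    entropy descriptors per structure), selects features with a two-phase
    moth flame optimization wrapper (variance fitness, then inter-class
    dispersion fitness), and classifies with an accuracy-weighted vote over
    six base learners. Ships a synthetic fundus-image generator with
    per-structure ground-truth masks so the whole pipeline is exercised
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    e1071,
    igraph,
    jsonlite,
    nnet,
    png,
    randomForest,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
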