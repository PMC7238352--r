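Package: biradsCAD
Title: BI-RADS Mass Classification from Mammographic Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline that assigns mammographic
    mass lesions to the four BI-RADS assessment categories B-2 through B-5.
    Regions of interest are contrast-enhanced by histogram equalization and
    segmented by seeded region growing over a sweep of grey-level thresholds.
    From each segmented mass 130 handcrafted BI-RADS descriptors are
    quantified: 9 shape features, mass size and patient age, 21 margin
    features derived from edge-probability waveforms, and 98 grey-level
    co-occurrence (Haralick) texture features. A modified genetic algorithm
    with integer feature-id chromosomes, elitism, roulette-wheel selection,
    (L-1)-point crossover and duplicate-repairing mutation searches the best
    feature subset of every size; a one-hidden-layer neural network supplies
    the fitness and the final classifier. Micro-averaged evaluation metrics,
    deterministic lesion phantoms and synthetic feature tables make the whole
    pipeline testable end to end without clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    nnet,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
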