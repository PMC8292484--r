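Package: octathresh
Title: Binarization Thresholds and Quantitative Metrics for OCTA Angiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates histogram-based binarization thresholds for en-face
    optical coherence tomography angiography (OCTA) reconstructions.
    Implements thirteen automatic and fixed thresholding techniques
    (IsoData, Huang, Intermodes, Li, Kapur maximum entropy, Mean, Tsai
    moments, Otsu, Percentile, Renyi entropy, Shanbhag, Yen, and fixed
    levels), overlap-based quality scoring of binarized images, vessel
    density, skeleton-based tortuosity and orientation dispersion metrics,
    foveal avascular zone (FAZ) detection, and cohort-level statistics
    (paired t-tests, two-rater intraclass correlation).  A seeded synthetic
    angiogram generator emulates superficial and deep capillary plexuses
    and choriocapillaris texture with ground-truth vessel and FAZ masks,
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
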