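Package: eggstage
Title: Automated Staging of Drosophila Egg Chambers from DAPI Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Morphometric staging of Drosophila melanogaster egg chambers
    from single-plane DAPI images. Segments the chamber of interest
    (scaled Otsu thresholding, average filtering, largest-component
    extraction and Chan-Vese active contours), measures its size as the
    convex-hull area of the segmented nuclei, derives the posterior-
    anterior axis and aspect ratio by principal component analysis,
    estimates oocyte size along the middle axis, scores follicle-cell
    uniformity by a 12-sector density distribution and its Delta-distance
    to uniform, detects stage-specific signals (polytene blob
    fragmentation, centripetal follicle-cell migration), and classifies
    developmental stage 2-12 with cumulative-logit ordinal regression plus
    a two-Gaussian intersection rule separating stages 8 and 9. Includes a
    synthetic DAPI-like image generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
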