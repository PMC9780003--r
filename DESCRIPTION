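Package: tonguetex
Title: Tongue Texture Classification via Coating Separation, Inpainting and
    Residual Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of tongue texture (tough/normal/tender)
    from segmented tongue photographs. Separates tongue coating from tongue
    body by fitting a Gaussian mixture model to pixel colors with EM,
    harvests body patches by coverage-filtered sliding windows, removes the
    coating by coarse-to-fine generative inpainting with a contextual
    attention layer, and classifies body texture with a configurable
    bottleneck residual network. Includes a synthetic tongue-image generator
    with ground-truth masks so the whole pipeline can be exercised and
    validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
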