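Package: texdiv
Title: Woody Plant Species Diversity from High-Resolution Image Texture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating woody-plant species diversity
    (Shannon index) from the texture of high-resolution multispectral imagery
    in savanna environments. Provides a synthetic savanna scene simulator,
    vegetation-index based woody masking over image segments, moving-window
    gray-level co-occurrence matrix (GLCM) texture statistics per spectral
    band, circular-plot zonal aggregation, exhaustive all-possible-subsets
    regression ranked by AIC with adjusted R-squared and RMSE reporting, and
    residual-correlation comparison of competing models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
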