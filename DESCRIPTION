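Package: mammodensity
Title: Mammographic Breast Density Quantification and Spatial Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Quantifies mammographic breast density from masked grayscale
    mammograms by maximum-entropy (Kapur) thresholding, computes overall,
    regional (8 x 6 tile grid) and zonal (posterior/middle/anterior) percent
    density, measures spatial autocorrelation of regional density with
    Moran's I under inverse-square-distance weights, classifies clustered /
    random / scattered patterns, and runs the cohort-level comparisons of
    density with age and BI-RADS density groups. Includes a synthetic
    MLO-view phantom and cohort generator with exported ground truth so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
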