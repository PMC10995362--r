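Package: myoretina
Title: Cone Mosaic Morphometry, Choroidal Vascularity, and Contrast
    Sensitivity Analysis for Myopia Imaging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for studies relating retinal
    microstructure to spatial vision in high myopia. Detects cone
    photoreceptors in adaptive-optics fundus image regions of interest and
    computes density, spacing, and Voronoi regularity; quantifies choroidal
    thickness and the choroidal vascularity index (CVI) from OCT B-scans by
    boundary flattening and Niblack local thresholding; estimates contrast
    sensitivity functions with the Bayesian adaptive Psi method and
    summarizes them as the area under the log CSF (AULCSF) and the cut-off
    spatial frequency; and reproduces the cohort statistics stage (group
    comparisons, correlations, univariate-to-multivariate regression
    screening) together with repeatability statistics (ICC, coefficient of
    repeatability). Includes synthetic generators for cone mosaics, choroid
    phantoms, simulated 2AFC observers with truncated log-parabola CSFs, and
    a study cohort, so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deldir,
    jsonlite,
    digest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png
Config/testthat/edition: 3
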