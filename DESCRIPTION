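Package: hcgtexture
Title: Quantitative Structural Texture Analysis of Hyperchromatic Crowded
    Cell Groups in Cervical Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the three-dimensional structure of
    hyperchromatic crowded cell groups (HCGs) on liquid-based cervical
    cytology images. Converts 24-bit micrographs to 8-bit gray scale,
    extracts region-of-interest gray-level histograms, and computes the
    per-cluster texture statistics used in cytology screening research:
    the histogram mode ("8-bit gray-scale value") and spreadsheet-definition
    skewness and kurtosis. Estimates cluster thickness from Z-stacks by a
    variance-of-Laplacian depth-from-focus profile, and runs the full group
    comparison battery (tie-corrected Kruskal-Wallis, Steel-Dwass all-pairs
    post hoc, ROC curves with Youden cut-offs, Pearson correlation, and
    interaction-term multiple regression). A seeded synthetic brightfield
    cluster simulator with multiplicative (Beer-Lambert style) absorbance
    and distance-proportional defocus provides ground-truth studies for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
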