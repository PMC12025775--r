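Package: tearllt
Title: Lipid Layer Thickness Estimation from Tear-Film Interferograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates tear-film lipid layer thickness (LLT) from Placido
    tear-film-analyzer interference-color images. Every pixel of a
    lower-cornea region of interest is classified to the nearest entry of a
    thickness-to-color lookup table by Euclidean distance in RGB space, the
    mean classified thickness is linearly calibrated, and the analyzed region
    is split into upper and lower sections to quantify the vertical lipid
    distribution. Includes blink-anchored analysis-frame selection from video
    frame sequences, a thin-film interference forward model for generating
    lookup tables and synthetic interferograms, a two-group pre/post cohort
    simulator parameterised by published dry-eye summary statistics, and the
    accompanying statistical stage (Kolmogorov-Smirnov normality screening,
    paired and independent t tests, change-score comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
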