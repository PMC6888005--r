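Package: compostvision
Title: Color and Texture Image Analysis of Composted Material
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Objective comparison of the appearance of composted material
    from sample photographs. Extracts 17 color and texture parameters per
    image (RGB channel means and medians, weighted-luminance grayscale
    statistics, white-pixel percentages at four binarization thresholds,
    histogram entropy, and four Haralick statistics from symmetric 8-level
    gray-level co-occurrence matrices averaged over four directions) and
    compares groups of composting experiments run under favorable versus
    unfavorable conditions with the Mann-Whitney U test and absolute
    percentage differences. Includes a seeded synthetic image generator
    emulating dark compost matrix with bright straw-like streaks, so the
    whole pipeline is testable without the original photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jpeg,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
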