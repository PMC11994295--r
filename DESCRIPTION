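Package: sampcov
Title: Inventory Completeness and Environmental Bias of Species Occurrence Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify how mobilising natural-history-collection
    records changes the completeness and bias of species occurrence data.
    Implements quality filtering and rule-based cross-dataset deduplication of
    Darwin-Core-like occurrence tables; per-grid-cell inventory completeness
    from species accumulation curves with Clench asymptote fitting and
    well-sampled cell classification; climate-space typing of grid cells by
    binning the first two principal components of a bioclimatic layer stack,
    with min-max climate-rarity scores; and sampling-bias statistics
    (Schoener's D niche overlap against a resampling null, two-sample
    Kolmogorov-Smirnov tests on climate axes, kernel density profiles).
    Includes a seeded synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
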