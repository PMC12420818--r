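Package: kinetoquant
Title: Quantification of Kinetochore and Pericentromere Fluorescence Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying mitotic fluorescence microscopy images:
    per-kinetochore protein recruitment relative to a reference kinetochore
    marker with mask-aware local background correction, chromatin and
    pericentromere region-level measurements with cytoplasmic correction and
    DNA normalisation, line-profile analysis of inter- and intra-kinetochore
    distances via Gaussian peak fitting, and the accompanying nonparametric
    statistics (Kruskal-Wallis with Dunn's post hoc comparisons). Includes a
    synthetic mitotic-image generator with full ground truth (PSF-blurred
    spots, pericentric bands, chromatin regions, Poisson and read noise) so
    every pipeline stage can be validated without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
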