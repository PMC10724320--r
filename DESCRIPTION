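Package: ihcscore
Title: Quantification of Nuclear Immunohistochemical Granule Staining and
    Vessel Density
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible pipeline for scoring nuclear chromogen granule
    immunoreactivity in conjunctival epithelium: focus stacking of
    multi-focal-plane micrographs, detection of counterstained nuclei and
    intranuclear chromogen granules, five-way granule pattern
    classification with a four-category positivity scheme, per-specimen
    immunoreactivity percentages, and all-pairs group comparison with
    Tamhane's T2 test (Welch t statistics with a Sidak family-wise
    correction). Also computes vessel-pixel density in colour photographs
    via green-channel extraction, high-pass filtering, h-dome
    morphological reconstruction and thresholding, and ships a seeded
    synthetic-data generator (epithelial fields with ground-truth nuclei,
    granules and goblet cells; vessel images with known vessel fraction)
    so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
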