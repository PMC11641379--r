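Package: msntx
Title: Morphometric Similarity Networks and Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-subject morphometric similarity networks from regional
    cortical MRI features, contrasts the regional morphometric-similarity
    statistic between cerebrospinal-fluid biomarker-defined groups with
    covariate-adjusted linear models, links the resulting regional contrast
    map to a region-by-gene expression matrix through one-component partial
    least squares with permutation and bootstrap inference, and tests the
    derived gene lists for overrepresentation in user-supplied gene-set
    collections by Fisher's exact test. Includes an Allen-atlas-style
    microarray preprocessing chain (intensity filtering, differential
    stability probe selection, centroid-based sample assignment, scaled
    robust sigmoid normalization, donor averaging) and a synthetic-data
    generator that plants parameterized group effects, spatially covarying
    genes, and enriched gene sets so every stage is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
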