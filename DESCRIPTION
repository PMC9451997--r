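Package: sahmine
Title: Associative Classification of CT Texture Features for Subarachnoid
    Hemorrhage Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gray-level cooccurrence matrix (GLCM) texture features from
    grayscale CT-like images, binarization of feature records into a
    transactional attribute table, five frequent-itemset miners (exhaustive
    enumeration, Apriori, DHP, Partition, FP-growth) plus the weighted
    NCFP-growth variant with a dual support/interest-weight threshold, and a
    classification-association-rule (CAR) classifier built by database
    coverage pruning and evaluated with stratified k-fold cross-validation.
    Includes seeded generators for two-class textured images and
    planted-rule transaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
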