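Package: thyroquant
Title: Quantitative B-Mode Ultrasound Features for Thyroid Lesion Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts formula-defined quantitative features from 2D B-mode
    ultrasound images of thyroid lesions (morphology, parenchyma-normalized
    echogenicity, local-entropy and co-occurrence texture, margin sharpness and
    Kullback-Leibler boundary separability, calcification and anechoic-area
    descriptors), refines lesion masks by morphological opening plus an active
    contour, screens features across histological subtypes with Kruskal-Wallis
    and Dunn-Sidak tests, prunes collinear features, and classifies papillary,
    follicular and medullary carcinoma with a random forest evaluated by
    out-of-bag permutation importance. A seeded speckle phantom generator with
    per-image ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
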