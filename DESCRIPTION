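Package: acnegrade
Title: Acne Severity Grading with Lesion-Count Priors and Interval-Weight Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for facial acne severity assessment on an
    8-level treatment-intensity scale. Generates synthetic frontal-face images
    with ground-truth lesion annotations over nine lesion categories, detects
    lesions with a classical colour/shape detector evaluated by per-class
    average precision and recall, maps inflammatory lesion counts to a grading
    interval via a dermatologist-style prior rule, trains an ordinal image
    grader whose class probabilities are fused with the interval prior through
    fixed binary masks or learnable non-negative interval weights, and provides
    the inter-rater agreement machinery (linear weighted Cohen's kappa, rater
    ranking and panel selection, median consensus labels, intraclass
    correlation) used to validate such systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    digest,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
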