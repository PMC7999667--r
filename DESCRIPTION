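Package: aceipred
Title: Screening of ACE-Inhibitory Peptides by Pseudo Amino Acid
    Composition and Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for virtual screening of food-derived
    antihypertensive (angiotensin-converting-enzyme inhibitory) peptides.
    Encodes peptides as type-II pseudo amino acid composition (PseAAC)
    vectors built from six physicochemical property scales, constructs
    balanced positive/negative training sets with fragment-sampled
    negatives, fits four parameterised classifier families (gradient
    boosted trees, RBF support vector machine, random forest, k-nearest
    neighbours) behind one fit/predict-probability interface, evaluates
    them with stratified cross-validation (accuracy, sensitivity,
    specificity, precision, ROC/AUC with confidence intervals), and
    screens proteins by exhaustive k-mer digestion with a triple-repeat
    high-probability candidate rule. A synthetic-data generator emulating
    the compositional signal of ACE-inhibitory peptides makes the whole
    pipeline testable without external database downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
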