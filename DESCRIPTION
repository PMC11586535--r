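Package: caninemurmur
Title: Heart Murmur Grading and Preclinical MMVD Staging from Canine
    Phonocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and grades heart murmurs in electronic-stethoscope
    recordings of dogs and stages preclinical myxomatous mitral valve
    disease (MMVD).  Recordings are transformed into normalized
    log-spectrograms and graded on the five-level reduced murmur
    intensity scale (none, soft, moderate, loud, thrilling) by a
    bidirectional gated-recurrent-unit network that is pretrained on a
    binary murmur-detection task and transferred to the ordinal grading
    task by replacing its output layer.  Includes a synthetic
    phonocardiogram and cohort generator for end-to-end testing,
    covariate-minimization cohort splitting, a repeated split/fine-tune
    evaluation protocol with bootstrap confidence intervals and
    vertically averaged ROC curves, and the ACVIM echocardiographic
    staging rules (LA/Ao, LVIDDN) with the loud-or-greater murmur
    probability rule for separating stage B1 from B2.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
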