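Package: zipscore
Title: Zero Interaction Potency Scoring of Drug Combination Dose-Response Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies synergy and antagonism in two-drug dose-response
    matrix screens. Implements the zero interaction potency (ZIP) reference
    model and its delta score, which measures how much one drug shifts the
    potency of the other's log-logistic dose-response curve, together with
    the classical highest-single-agent (HSA), Bliss independence and Loewe
    additivity references, Combination Index and interaction-index alpha,
    and a panel of matrix-level comparison scores (NumExcess, ExcessHSA,
    MedianExcess, LS3x3, beta, gamma). Provides robust bounded log-logistic
    curve fitting that tolerates noisy or irregular plate data, per-dose-pair
    interaction landscapes with CSV/PNG export, parametric-bootstrap
    significance estimates for delta, monotherapy-variance matrix resampling,
    readers and writers for long-format and matrix-format combination
    tables, a synthetic-matrix generator with known interaction structure,
    and a command-line interface for batch scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'logistic-fit.R'
    'reference-models.R'
    'zip-delta.R'
    'comparison-scores.R'
    'significance.R'
    'io.R'
    'synthetic.R'
    'landscape-export.R'
    'zipscore-package.R'
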