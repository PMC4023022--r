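Package: likertbin
Title: Binomial and Mixed-Binomial Category Response Models for
    Likert-Type Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits one-parameter binomial, two-parameter normal, and mixed
    (two-component) binomial category response models to per-item
    Likert response distributions by exhaustive Pearson chi-square
    minimisation, with AIC-based and improvement-rule model selection.
    Detects response-style biases (single-category over/under-use,
    V-shaped midpoint avoidance) against the binomial benchmark,
    quantifies how much uniform random noise the binomial fit tolerates
    by simulation and back-estimates noise levels from observed misfit,
    and generates synthetic item banks with a complete truth log for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
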