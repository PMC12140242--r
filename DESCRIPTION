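Package: ensembert
Title: Questionnaire Score Inference from Social-Media Posts via Dense
    Retrieval and an Ensemble Attention Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-item and overall Beck Depression Inventory-II
    (BDI-II) scores from a user's social-media post history. For each
    questionnaire item the most relevant posts are selected by zero-shot
    dense retrieval (dot-product similarity of frozen sentence embeddings,
    top-k), and a small trainable head combines cross-attention of the
    item description over the retrieved posts, cosine scoring against the
    four answer-choice embeddings, and an ensemble layer into a
    probability distribution over the item's 0-3 score. Includes
    multi-granularity evaluation (item, overall score, severity
    category), internal-consistency psychometrics (Cronbach's alpha,
    corrected item-total correlations), and a synthetic-cohort generator
    with a planted semantic signal so the whole pipeline is testable
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
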