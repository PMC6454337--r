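Package: gstag
Title: Geriatric Syndrome Construct Tagging in Clinical Notes with Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies mentions of ten geriatric-syndrome constructs
    (falls, dementia, malnutrition, incontinence, and others) in free-text
    clinical notes with a feature-rich linear-chain conditional random
    field, and aggregates token-level predictions to phrase, note, and
    patient determinations. Includes rule-based clinical text
    preprocessing (section and sentence segmentation, tokenization,
    negation/uncertainty/subject detection), Basic/Enhanced/Global
    feature extraction with ICD9 lexicon features, CRF training by
    stochastic gradient descent or L-BFGS with exact forward-backward and
    Viterbi inference, four-level span evaluation with micro and macro
    averaging and McNemar's test, bigram language-model perplexity and
    out-of-vocabulary error analysis, and a seeded generator of synthetic
    annotated corpora emulating the statistical structure of geriatric
    EHR notes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
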