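Package: gestaltN400
Title: Sentence Gestalt and Surprisal Correlates of the N400
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a Sentence Gestalt model of predictive sentence
    comprehension (an LSTM update network probed with role-filler queries)
    together with a matched next-word-prediction language model, extracts
    per-word Semantic Update and surprisal, and relates these model-based
    predictors to single-trial N400 amplitudes and EEG time courses through
    baseline-covaried linear mixed-effects models, likelihood-ratio model
    comparison, mass-univariate time-course regression with false-discovery-rate
    control, and fractional-area latency analysis. Includes generators for
    frame-annotated micro-language corpora with controllable event statistics
    and for synthetic single-trial ERP data with planted effects, so that every
    stage of the analysis chain can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
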