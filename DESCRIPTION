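Package: dassxdt
Title: Explainable Severity Assessment of Anxiety, Stress and Depression
    from DASS-42 Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for multi-level psychological-disorder
    assessment from DASS-42 questionnaire responses. Encodes raw ordinal
    responses onto the 0-3 rate-point scale, computes per-disorder Weight
    Scores and five-level severity labels (Normal to Extremely Severe),
    eliminates low-relevance queries via a mean rate-point relevance
    threshold (Q-Prioritization), trains an entropy/information-gain
    decision tree wrapped in a repeated random-oversampling loop that
    escalates the minority sampling rate while validation accuracy
    improves, and explains individual predictions through permutation
    feature importance, contrastive pertinent-positive/negative query
    sets, prototype-guided counterfactual deltas, and templated clinician
    feedback. Includes a synthetic response generator with controllable
    severity mixture, class imbalance and noise, a metrics/comparison
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
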