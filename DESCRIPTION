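Package: fearcortex
Title: Analysis of Auditory Cortical Discriminability and Differential Fear Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal two-photon calcium-imaging
    cohorts in a differential fear conditioning (DFC) paradigm: freezing and
    learning-specificity scoring from motion-index traces, single-neuron
    frequency tuning and CS+/CS- discriminability (Z_diff) with
    permutation-null inference, linear-SVM population decoding with
    neuron-count-matched resampling, bootstrap rank-correlation inference,
    landmark-based longitudinal ROI tracking, a synthetic-cohort generator
    with programmed ground truth, and a rate-based thalamo-cortico-amygdala
    circuit model with Delta-rule plasticity and cortical tuning drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
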