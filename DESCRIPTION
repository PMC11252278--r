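Package: audiencesync
Title: Surrogate-Tested Physiological Synchrony in Concert Audiences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying interpersonal physiological synchrony in
    audiences sharing a stimulus. Implements the surrogate synchrony (SUSY)
    statistic (segment-wise lagged cross-correlations, Fisher-Z aggregation,
    segment-shuffle surrogate null, effect sizes), its extension from dyads to
    whole audiences via per-participant synchrony contributions, derivation of
    feature series (heart rate, RMSSD heart-rate variability, respiration rate,
    respiration behaviour, phasic skin conductance) from raw-level signals, and
    random-intercept mixed models linking synchrony contributions to affect,
    personality and experience covariates. A synthetic-data module simulates
    audiences whose physiology is coupled to a shared latent driver, with known
    ground truth, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
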