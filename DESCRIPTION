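Package: emgintent
Title: Intent Prediction of Multi-Axial Ankle Motion from Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying step-by-step prediction of multi-axial
    ankle-foot motion (dorsiflexion, foot flat, plantarflexion, eversion,
    inversion) from three lower-leg surface EMG channels (tibialis anterior,
    medial and lateral gastrocnemius). Includes a seeded synthetic gait EMG
    generator with walking-style, terrain and electrode-shift conditions; the
    standard conditioning chain (Butterworth band-pass, MVC amplitude
    normalization, linear-envelope low-pass); windowed time-domain features
    (VAR, WL, IEMG, AR(2), RMS, MAV); four classifiers (LDA, CART, a
    deterministic muscle-ordering rule, and a majority-else-deterministic
    voting scheme); three prediction approaches (generic, biased generic,
    walking style); and a factorial evaluation harness with confusion
    matrices and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rpart,
    signal,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
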