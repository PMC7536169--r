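Package: tpt
Title: Headless Toolkit for the Timbre Perception Test
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scriptable implementation of a slider-based timbre perception
    test: additive synthesis of complex-tone stimuli along three timbre
    dimensions (amplitude envelope, spectral flux, spectral centroid) with
    calibrated slider-to-parameter link functions, acoustic verification
    measurements, test-session construction, equal-frequency bin scoring
    with persistent bin boundaries for retest scoring, a psychometric
    evaluation suite (Cronbach's alpha, McDonald's omega-total, two-way
    random absolute-agreement ICC, KMO, Bartlett's sphericity test,
    minimum-residual exploratory factor analysis with parallel analysis,
    Benjamini-Hochberg-corrected Spearman correlations), and a synthetic
    respondent simulator with a latent-ability noise model so the whole
    pipeline runs end to end without human participants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
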