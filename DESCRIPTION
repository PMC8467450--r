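Package: pathsta
Title: Bayesian Network Scoring of NF-kB Signal Transduction Pathway
    Activity in Transcriptomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the functional activity of the NF-kB signaling
    pathway in individual transcriptomic profiles with a three-layer
    Bayesian network: a latent transcription-complex activity node, a
    layer of target-gene transcription states, and Gaussian
    class-conditional probeset-intensity evidence. Provides exact
    tree-structured inference, calibration on labelled reference
    profiles, 0-100 activity-score normalization, a synthetic-data
    generator with known ground truth for cohort and paired longitudinal
    study designs, cohort-level statistics (one-way ANOVA with Tukey
    correction, quartile summaries, per-patient trajectories), and
    paired fold-change and differential-correlation analyses of the six
    pro-survival BCL-2 family transcripts around disease relapse.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
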