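Package: eegmicrostates
Title: Resting-State EEG Microstate Segmentation and Paired-Design Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state EEG microstate analysis: global field
    power (GFP) computation and peak extraction, polarity-invariant modified
    k-means clustering of GFP-peak topographies, global explained variance
    (GEV), two-level (individual then grand-mean) template derivation,
    shared-variance sorting of maps to reference templates, backfitting with
    nearest-neighbour label interpolation, and per-class temporal features
    (mean duration, occurrence, coverage). A synthetic-data module generates
    multichannel recordings with planted microstate structure so every stage
    can be validated by parameter recovery. A statistics layer provides
    paired t-tests with paired Cohen's d, confidence-interval inversion,
    Bonferroni-adjusted significance levels, large-effect selection and
    Pearson correlations for pre/post designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, signal, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
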