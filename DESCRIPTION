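Package: svtephys
Title: Electrophysiological Indices for Sports Vision Training Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and analysis chain for EEG and visual-evoked-potential
    (VEP) outcomes in crossover sports-vision-training studies. Implements
    per-epoch relative power spectral density at 1-Hz resolution with
    overlay-based validity rules, the frontal theta/gamma Short-Term Memory
    Load Index (STMLI) with 5% trimmed-mean aggregation per task, transient
    VEP N75-P100-N135 component extraction from sweep averages, and the
    repeated-measures statistical design layer (screening, doubly
    multivariate RM-MANOVA with sphericity corrections, Sidak pairwise
    comparisons, and a-priori power analysis for within-between
    interactions). Ships seeded synthetic-data generators for EEG, VEP
    sweeps, and crossover behavioral tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    nortest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
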