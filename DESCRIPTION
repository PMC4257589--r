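Package: microstate
Title: Resting-State EEG Microstate Analysis and Test-Retest Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of multichannel resting-state EEG into microstates:
    global field power (GFP) peak extraction, polarity-invariant topographic
    clustering (topographic atomize-and-agglomerate hierarchical clustering and
    modified k-means), back-fitting of template maps, and extraction of the
    classical microstate features (mean lifespan, frequency of appearance,
    coverage fraction). Includes the statistical machinery needed to assess
    test-retest reliability of those features across repeated sessions:
    Cronbach's alpha, the standard error of measurement (SEM), the smallest
    detectable change, and topographic analysis of variance (TANOVA) by
    randomization of the global map dissimilarity. A synthetic-EEG generator
    with known microstate ground truth supports end-to-end validation, and a
    study driver reproduces the full strategy x algorithm x montage analysis
    grid on synthetic or user-supplied recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
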