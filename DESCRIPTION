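Package: clickpop
Title: Temporal-to-Spatial Transformation of Click-Sequence Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs temporally patterned click-train stimuli built from
    permuted inter-click-interval blocks, simulates click-locked primary and
    interval-context-tuned secondary auditory spike responses with ground-truth
    labels, sorts spikes from raw extracellular traces (Butterworth filtering,
    spline-aligned snippets, PCA + Haar-wavelet features, EM Gaussian-mixture
    clustering), classifies units as primary or secondary by PSTH-to-stimulus
    cross-correlation, quantifies sequence discriminability of population-vector
    phase-space trajectories by ROC analysis, simulates a critically tuned
    reverberant linear network with an antisymmetric coupling matrix, and
    analyzes reset-go operant trial logs with d-prime learning curves and
    catch-trial interruption ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    mclust,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
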