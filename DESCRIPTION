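Package: anmapr
Title: Activation Network Mapping with Transcriptomic and Neurotransmitter
    Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes heterogeneous task-fMRI activation coordinates to a
    common brain network by seed-to-voxel functional connectivity against a
    normative resting-state connectome ("activation network mapping"), with
    overlap-consensus construction, robustness analyses (threshold and
    seed-radius sweeps, leave-one-experiment-out, Dice similarity), ROI-based
    specificity contrasts (Cohen's d on z-statistic distributions),
    transcriptomic decoding by partial least squares with Moran spectral
    randomization spatial nulls and bootstrap gene scoring, neurotransmitter
    system decoding by relative-importance (LMG) regression on receptor
    density maps, generic term-map decoding, and a synthetic-data generator
    that plants known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
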