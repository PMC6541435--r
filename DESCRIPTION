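Package: threshdr
Title: Thresholded Dual Regression for Overlapping Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how spatial overlap between functional brain
    networks biases node-based functional connectivity estimated with group
    spatial ICA followed by dual regression, and for correcting that bias with
    thresholded dual regression. Implements the four-stage thresholded dual
    regression pipeline (spatial regression, temporal regression,
    Gaussian/Gamma mixture-model thresholding of subject maps, and a final
    spatial regression against thresholded maps), temporal network matrices
    and spatial overlap matrices, two multi-subject resting-state fMRI
    simulators with full ground-truth records (a two-node overlapping
    outer-product simulator and a parcel-based mode simulator with warps, HRF
    convolution and structured noise), and evaluation metrics comparing
    estimated maps, timeseries and edges against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    ica,
    clue,
    jsonlite,
    yaml,
    RNifti,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
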