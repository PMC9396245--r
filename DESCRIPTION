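Package: hobfn
Title: High-Order Brain Functional Networks from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and classification of high-order brain functional
    networks from multichannel EEG. Low-order networks are built per sliding
    window with the phase lag index or Pearson correlation; the per-pair
    connectivity time series are clustered hierarchically across subjects and
    a small "correlation's correlation" high-order network is computed from
    the cluster-mean series. Features from both network orders are screened
    by two-sample t-tests, selected by the LASSO, and classified with linear
    support-vector machines whose decision scores are fused by a weighted
    linear combination, all under nested repeated stratified cross-validation.
    A seeded synthetic-EEG generator with planted phase coupling, modular
    coupling dynamics, and a group difference in high-order structure supports
    end-to-end validation without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'cli.R'
    'cv.R'
    'edf.R'
    'eeg-io.R'
    'features.R'
    'hobfn.R'
    'lobfn.R'
    'pipeline.R'
    'preprocess.R'
    'regions.R'
    'synth.R'
    'utils.R'
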