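Package: causalrca
Title: Causality Detection and Root-Cause Analysis for Multichannel Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified toolkit for data-driven causality detection and root-cause
    analysis on multichannel, uniformly sampled recordings such as industrial
    process measurements and intracranial EEG. Implements bivariate and
    multivariate Granger causality with BIC order selection, the directed
    transfer function (DTF) and partial directed coherence (PDC) together with
    full-frequency and spectrum-weighted variants, transfer entropy and direct
    (conditional) transfer entropy with indirect-edge pruning, convergent cross
    mapping with library-length convergence analysis, cross-correlation lag
    directionality and the phase slope index. A Monte-Carlo surrogate-data
    framework (IAAFT, phase randomization, shuffling) provides significance
    thresholds; causal graphs, per-node information outflow, sliding-window
    dynamic analysis and source ranking support localization of fault origins
    and seizure onset zones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
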