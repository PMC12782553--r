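Package: barcodeRNN
Title: Barcode Memory in Chaotic Recurrent Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a hippocampal memory model in which a chaotic
    recurrent rate network transforms smoothly tuned place inputs into
    sparse, decorrelated "barcode" activity patterns, binds episodic
    content (location and a scalar seed signal) to those barcodes by
    Hebbian plasticity, and recalls memories by attractor pattern
    completion with a tunable search radius. Includes the three-cache
    behavioural tasks (Cache Presence and Cache Location), ablation
    model factories, Poisson spike-count correlation analyses,
    site-distance calibration, a successor-representation hybrid with a
    recurrence-gain projection decomposition, a feedforward barcode
    alternative, Gaussian-process place inputs, and experiment
    orchestration with plain-text configs and tabular outputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
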