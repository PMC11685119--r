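Package: eegadapt
Title: Cross-Subject EEG Emotion Classification with Dual-Branch Spatial
    Features and Domain-Adversarial Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns multichannel EEG into per-band differential-entropy
    features and two complementary spatial representations (a scalp-grid
    activity map and an electrode topology graph), extracts features with a
    dual-branch network (graph attention over the electrode graph, a
    modified residual CNN over the activity map, concatenation fusion), and
    trains it domain-adversarially with a gradient-reversal layer for
    cross-subject emotion classification under leave-one-subject-out
    evaluation. Includes a synthetic multi-subject cohort generator with
    class-conditional band-power structure and per-subject domain shift, an
    ablation harness, and a command-line interface. The neural-network
    forward and backward passes are implemented in base R matrix code sized
    for scalp-map inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
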