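Package: chanattn
Title: Cross-Channel Patch-Wise Attention Networks for Multi-Channel
    Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of multi-channel fixed-rate sensor signal
    windows (wearable IMU, EEG and similar modalities) via log-magnitude
    STFT spectrograms and an adaptive attention-convolution network.
    Channels attend to each other over small sliding spectrogram patches;
    attention heads are generated and mixed by 1x1 convolutions over the
    head axis, gated by a learned head-importance layer, and classified by
    a small MLP.  The trunk is channel-count agnostic, so a model
    pretrained on one sensor layout can be fine-tuned on another by
    replacing only the final classification layer.  Includes a seeded
    synthetic-signal generator, a training/fine-tuning harness with
    hand-written reverse-mode gradients, binary containers for datasets
    and checkpoints, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
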