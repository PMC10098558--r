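Package: imuhar
Title: End-to-End Neural Network Classification of Infant Movement from
    Multi-Sensor Wearable IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for human activity recognition from multi-sensor inertial
    measurement unit (IMU) recordings, built around the movement-classification
    problem of limb-worn accelerometer/gyroscope sensors on infants. Implements
    the raw packet-stream preprocessing pipeline (timebase interpolation,
    gyroscope bias removal, median filtering, sliding-window framing), a
    336-dimensional hand-crafted feature baseline with a linear SVM, five
    sensor-encoder neural architectures (dense, 1-D CNN, and three 2-D
    channel-fusion CNN variants) crossed with five time-series modules (dense,
    LSTM, GRU, bidirectional GRU, WaveNet-style gated dilated convolutions),
    training-time data augmentation (input/bottleneck dropout, sensor dropout,
    Euler-angle sensor rotation, sinusoidal time warping), a training and
    cross-validation harness with unweighted average F1 evaluation, robustness
    simulations (packet loss, sensor dropout), and a synthetic multi-IMU data
    generator with Markov-chain activity labels. The neural layers,
    backpropagation and Adam optimizer are implemented in base R over BLAS
    matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
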