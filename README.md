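# imuhar

Neural-network classification of infant movement from multi-sensor wearable
IMU recordings, in pure R.

Four limb-mounted inertial measurement units stream triaxial accelerometer
and gyroscope packets at 52 Hz; the task is to label every 2.3-second frame
with one of seven movement categories (Still, Proto movement, Turn L/R,
Pivot L/R, Crawl commando). `imuhar` implements the full stack for this
human-activity-recognition problem:

* **Preprocessing** — linear interpolation of jittered packet timestamps onto
  a uniform 52 Hz timebase, gyroscope-bias removal (mean of the
  minimum-variance 64-sample segment), 5-sample median filtering, and
  windowing into a `(n_frames, 24, 120)` tensor (50% overlap).
* **Baseline** — 14 hand-crafted features per channel (336 per frame) and a
  standardized linear-SVM classifier.
* **Five sensor encoders × five time-series models** — dense, 1-D CNN and
  three 2-D channel-fusion CNN encoders (individual paths, individual +
  shared paths, and a sensor-independent shared submodule), crossed with
  dense, LSTM, GRU, bidirectional-GRU and WaveNet-style gated dilated
  convolution temporal modules (kernel 5, dilations 1/2/4/8, residual and
  skip connections, 61-frame receptive field). Layers, backprop and Adam are
  implemented in base R over BLAS; all gradients are finite-difference
  checked in the tests.
* **Augmentation** — input/bottleneck dropout (30%), sensor dropout (30%),
  per-sensor Euler rotations (±10°), sinusoidal time warping.
* **Training & evaluation** — Adam (lr 1e-3) on 100-consecutive-frame
  minibatches with early stopping; unweighted average F1 (UWAF) with
  record-level bootstrap CIs and Wilcoxon comparisons; sevenfold
  subject-disjoint cross-validation; robustness grids for sensor dropout
  (all 1- and 2-sensor combinations) and packet loss (25% / 50% in 4-sample
  bursts, 5 repetitions).
* **Synthetic data** — a seeded multi-IMU generator (Markov activity labels,
  class/limb signal signatures, gravity drift, gyro bias, packet jitter,
  optionally the skewed study-like class distribution) standing in for the
  non-public clinical dataset.

The evaluation metric is the unweighted average of per-class F1 scores,

    F1_c = tp_c / (tp_c + 0.5 (fp_c + fn_c)),    UWAF = mean_c F1_c,

which is robust to the heavy class skew typical of infant recordings.

## Worked example

```r
library(imuhar)

# 8 seeded synthetic recordings (3 min each, uniform class mix),
# preprocessed into frame tensors + labels
cfg <- synthetic_config("easy", seed = 11)
ds  <- preprocess_dataset(make_benchmark_dataset(cfg))

# train the best system end-to-end on 6 recordings
model <- train_system(encoder_spec("conv2d_si"), temporal_spec("wavenet"),
                      ds[1:6], cfg = train_config(max_epochs = 40,
                                                  patience = 12, seed = 42))

# evaluate on the 2 held-out recordings
evaluate_system(model, ds[7:8])
#> <eval_report> UWAF 0.9691 over 310 frames / 2 recordings
#>   Still          F1 0.9901
#>   Proto          F1 0.9600
#>   TurnL          F1 0.9630
#>   TurnR          F1 0.9725
#>   PivotL         F1 0.9697
#>   PivotR         F1 0.9538
#>   CrawlCommando  F1 0.9744

# robustness: average UWAF over the four 1-sensor-dropped conditions
sensor_dropout_eval(model, ds[7:8], n_dropped = 1)$mean_uwaf
#> [1] 0.6551193
```

The UWAF of ~0.97 says the trained system recovers essentially all frame
labels of unseen recordings of this separable benchmark; the drop to ~0.66
with one sensor removed shows an unaugmented model leans on all four limbs.
Training with `aug = augmentation_preset("drs")` (sensor dropout) lifts the
dropped-sensor score to ~0.9 at roughly unchanged clean performance.

Parameter and cost accounting for embedded use:

```r
count_parameters(build_encoder(encoder_spec("conv2d_si")))  # 82920
estimate_flops(encoder_spec("conv2d_si"))  # ~0.26 MFLOPs per sensor per frame
# 20 bottleneck features per sensor compress the raw frame 36:1
(24 * 120) / encoder_spec("conv2d_si", per_sensor_dim = 20)$bottleneck_dim
#> [1] 36
```

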