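test_that("per-class F1 and UWAF follow the tp / (tp + 0.5 (fp + fn)) form", {
  # perfect diagonal
  conf <- diag(c(5L, 3L, 2L, 4L, 1L, 2L, 6L))
  expect_equal(uwaf(conf), 1)
  # hand-evaluated two-class case: [[8, 2], [3, 7]]
  conf2 <- matrix(c(8L, 3L, 2L, 7L), 2, 2)
  f1 <- f1_scores(conf2)
  expect_equal(unname(f1), c(8 / 10.5, 7 / 9.5))
  expect_equal(uwaf(conf2), mean(c(8 / 10.5, 7 / 9.5)))
  # one class fully misclassified, others perfect
  conf3 <- diag(rep(4L, 7))
  conf3[2, 2] <- 0L
  conf3[2, 1] <- 4L   # class 2 always called class 1
  f13 <- f1_scores(conf3)
  expect_equal(unname(f13[2]), 0)
  expect_equal(uwaf(conf3), mean(f13))
  expect_error(uwaf(matrix(0L, 7, 7)), "empty")
})

test_that("UWAF is invariant under simultaneous class permutation", {
  set.seed(1)
  truth <- sample(7, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.8, truth, sample(7, 200, replace = TRUE))
  u0 <- uwaf(confusion_matrix(truth, pred))
  perm <- sample(7)
  u1 <- uwaf(confusion_matrix(perm[truth], perm[pred]))
  expect_equal(u1, u0)
  # absent classes are excluded from the unweighted average
  conf <- matrix(0L, 7, 7)
  conf[1:3, 1:3] <- diag(c(5L, 5L, 5L))
  expect_equal(uwaf(conf), 1)
})

test_that("bootstrap CI brackets the mean and degenerates correctly", {
  expect_equal(unname(bootstrap_ci(rep(0.8, 10), n_iter = 500)),
               c(0.8, 0.8))
  set.seed(2)
  scores <- runif(15, 0.6, 0.9)
  ci <- bootstrap_ci(scores, n_iter = 3000)
  expect_lte(ci["lo"], mean(scores))
  expect_gte(ci["hi"], mean(scores))
  expect_warning(bootstrap_ci(0.5), "single")
})

test_that("bootstrap CI has near-nominal coverage on Gaussian scores", {
  set.seed(3)
  hits <- 0L
  n_trials <- 200L
  for (i in seq_len(n_trials)) {
    scores <- rnorm(20, 0.75, 0.05)
    ci <- bootstrap_ci(scores, n_iter = 400)
    if (ci["lo"] <= 0.75 && ci["hi"] >= 0.75) hits <- hits + 1L
  }
  # percentile bootstrap at n = 20 undercovers slightly; allow a wide band
  expect_gt(hits / n_trials, 0.85)
  expect_lte(hits / n_trials, 1.0)
})

test_that("rank-sum comparison matches exact enumeration at tiny n", {
  a <- c(0.81, 0.74, 0.69)
  b <- c(0.55, 0.60, 0.77)
  expect_equal(compare_modules(a, b), enum_wilcoxon_p(a, b), tolerance = 1e-12)
  a2 <- c(1.2, 3.4, 2.2, 5.0)
  b2 <- c(0.1, 0.9, 2.9)
  expect_equal(compare_modules(a2, b2), enum_wilcoxon_p(a2, b2),
               tolerance = 1e-12)
  # symmetry of the two-sided test
  expect_equal(compare_modules(a, b), compare_modules(b, a))
  # identical samples: p ~ 1
  expect_gt(compare_modules(c(1, 2, 3, 4), c(1.01, 2.01, 2.99, 3.99)), 0.6)
  expect_error(compare_modules(numeric(0), b), "non-empty")
})

test_that("packet loss zeroes the requested fraction in 4-aligned bursts", {
  set.seed(4)
  sig <- matrix(rnorm(24 * 4000), 24, 4000)
  sig[sig == 0] <- 1e-9
  expect_identical(simulate_packet_loss(sig, 0), sig)
  out1 <- simulate_packet_loss(sig, 1)
  expect_true(all(out1 == 0))
  out <- simulate_packet_loss(sig, 0.25)
  for (s in 1:4) {
    rows <- imuhar:::sensor_rows(s)
    zero_cols <- which(colSums(out[rows, ] == 0) == 6L)
    frac <- length(zero_cols) / 4000
    expect_lt(abs(frac - 0.25), 0.01)
    # every zero run is packet-aligned: run lengths are multiples of 4
    r <- rle(seq_len(4000) %in% zero_cols)
    expect_true(all(r$lengths[r$values] %% 4 == 0))
    expect_true(all((which(diff(c(0, seq_len(4000) %in% zero_cols)) == 1)) %% 4 == 1))
  }
  # frame-tensor form
  frames <- array(rnorm(10 * 24 * 120), c(10, 24, 120))
  fout <- simulate_packet_loss(frames, 0.25)
  zfrac <- mean(fout[, imuhar:::sensor_rows(1), ] == 0)
  expect_lt(abs(zfrac - 0.25), 0.02)
})

test_that("sensor-dropout evaluation enumerates the right combinations", {
  ds <- tiny_dataset()
  set.seed(5)
  model <- list(encoder = build_encoder(encoder_spec("conv1d")),
                temporal = build_temporal(temporal_spec("dense")))
  ev1 <- sensor_dropout_eval(model, ds[1], 1)
  expect_equal(nrow(ev1$per_combo), 4L)
  ev2 <- sensor_dropout_eval(model, ds[1], 2)
  expect_equal(nrow(ev2$per_combo), 6L)
  ev0 <- sensor_dropout_eval(model, ds[1], 0)
  expect_equal(ev0$mean_uwaf, evaluate_system(model, ds[1])$uwaf)
  expect_error(sensor_dropout_eval(model, ds[1], 4), "four")
})

test_that("training is deterministic from the seed and stops on patience", {
  ds <- tiny_dataset()
  cfg <- train_config(max_epochs = 3, patience = 5, seed = 11,
                      minibatch = 40)
  es <- encoder_spec("conv1d", bottleneck_dim = 32,
                     conv1d_channels = c(8, 8, 12, 12))
  ts <- temporal_spec("dense", d_in = 32, hidden_dim = 32)
  m1 <- train_system(es, ts, ds, cfg = cfg)
  m2 <- train_system(es, ts, ds, cfg = cfg)
  expect_identical(m1$history, m2$history)
  z1 <- encode(m1$encoder, ds[[1]]$frames[1:2, , ])
  z2 <- encode(m2$encoder, ds[[1]]$frames[1:2, , ])
  expect_identical(z1, z2)

  # patience: training on constant-label data converges immediately, so the
  # validation loss stops improving and the run ends after patience epochs
  ds_const <- lapply(ds, function(r) {
    r$labels <- factor(rep("Still", length(r$labels)),
                       levels = movement_classes())
    r
  })
  cfg2 <- train_config(max_epochs = 50, patience = 3, seed = 11,
                       minibatch = 40, lr = 0)   # lr 0: loss never improves
  m3 <- train_system(es, ts, ds_const, cfg = cfg2)
  expect_lte(m3$epochs_run, 1L + 3L)
  expect_error(train_system(es, ts, list()), "empty")
})

test_that("evaluation is deterministic and fold partitions are sound", {
  ds <- tiny_dataset()
  set.seed(6)
  model <- list(encoder = build_encoder(encoder_spec("conv1d")),
                temporal = build_temporal(temporal_spec("dense")))
  e1 <- evaluate_system(model, ds)
  e2 <- evaluate_system(model, ds)
  expect_identical(e1$uwaf, e2$uwaf)
  expect_equal(sum(e1$confusion),
               sum(vapply(ds, function(r) length(r$labels), numeric(1))))

  # 22 recordings into 7 folds: sizes in {3, 4}, disjoint, covering
  set.seed(7)
  folds <- imuhar:::make_folds(22, 7)
  sizes <- lengths(folds)
  expect_true(all(sizes %in% c(3L, 4L)))
  expect_equal(sort(unname(unlist(folds))), 1:22)
  expect_equal(sum(sizes), 22L)
})

test_that("cross-validation scores every recording once per repeat, never by its own model", {
  # 4 tiny recordings, 2 folds; inspect fold bookkeeping
  ds <- tiny4_dataset()
  tc <- train_config(max_epochs = 1, patience = 2, k_folds = 2,
                     n_repeats = 2, seed = 9, minibatch = 30)
  es <- encoder_spec("dense", bottleneck_dim = 16, dense_hidden = c(8, 8, 8))
  ts <- temporal_spec("dense", d_in = 16, hidden_dim = 16)
  rep_out <- crossvalidate(ds, es, ts, cfg = tc)
  expect_s3_class(rep_out, "eval_report")
  expect_length(rep_out$repeat_uwaf, 2L)
  expect_equal(rep_out$uwaf, mean(rep_out$repeat_uwaf))
  expect_equal(sort(unname(unlist(rep_out$folds))), 1:4)
  expect_false(any(is.na(rep_out$per_recording$uwaf)))
  expect_lte(rep_out$ci["lo"], mean(rep_out$per_recording$uwaf))
  expect_error(crossvalidate(ds[1:2], es, ts,
                             cfg = train_config(k_folds = 7)), "fewer")
})

test_that("the architectures grid emits exactly 25 system rows", {
  ds <- tiny4_dataset()
  cfg <- train_config(max_epochs = 0, seed = 10)  # build + score, no training
  grid <- run_experiment_grid("architectures", ds, cfg, test_fraction = 0.5)
  expect_equal(nrow(grid), 25L)
  expect_equal(nrow(unique(grid[, c("encoder", "temporal")])), 25L)
  expect_true(all(grid$uwaf >= 0 & grid$uwaf <= 1))
  expect_true(all(nchar(grid$config_hash) == 8L))
  expect_true(all(grid$seed == 10L))
})

test_that("the size-complexity grid reports params, MFLOPs and the bottleneck sweep", {
  ds <- tiny4_dataset()
  cfg <- train_config(max_epochs = 0, seed = 11)
  grid <- run_experiment_grid("size_complexity", ds, cfg, test_fraction = 0.5)
  expect_equal(nrow(grid), 25L + 3L)
  sweep_rows <- grid[grid$condition == "bottleneck_sweep", ]
  expect_equal(sort(sweep_rows$bottleneck), c(40L, 80L, 160L))
  expect_true(all(grid$n_params > 0))
  expect_true(all(grid$mflops > 0))
  # conv1d encoder has fewer parameters than dense in every pairing
  p_dense <- grid$n_params[grid$encoder == "dense" & grid$temporal == "dense"]
  p_conv <- grid$n_params[grid$encoder == "conv1d" & grid$temporal == "dense"]
  expect_lt(p_conv, p_dense)
})
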