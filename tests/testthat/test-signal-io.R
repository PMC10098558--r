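test_that("interpolation reproduces constant and affine signals exactly", {
  st_const <- make_test_stream(fun = function(t) rep(2.5, length(t)))
  out <- interpolate_to_uniform(st_const)
  # channel ch carries constant 2.5 + ch
  for (ch in 1:6) expect_equal(unname(out$signal[ch, ]),
                               rep(2.5 + ch, ncol(out$signal)))

  st_affine <- make_test_stream(fun = function(t) 3 * t - 1)
  out <- interpolate_to_uniform(st_affine)
  for (ch in 1:6) {
    expect_equal(unname(out$signal[ch, ]), 3 * out$times - 1 + ch,
                 tolerance = 1e-12)
  }
})

test_that("interpolation of a jittered sine matches the two-point oracle", {
  st <- make_test_stream(n = 96L, seed = 7)
  out <- interpolate_to_uniform(st)
  for (ch in c(1L, 4L)) {
    oracle <- naive_lin_interp(st$timestamps, st$samples[, ch], out$times)
    expect_equal(unname(out$signal[ch, ]), oracle, tolerance = 1e-10)
  }
})

test_that("interpolation at original sample times of a uniform stream is identity", {
  t <- (0:63) / 52
  samples <- sapply(1:6, function(ch) sin(t * ch))
  st <- raw_sensor_stream("RA", t, samples)
  out <- interpolate_to_uniform(st)
  expect_equal(out$times, t)
  expect_equal(unname(t(out$signal)), samples, tolerance = 1e-12)
})

test_that("raw streams reject malformed input", {
  t <- (0:7) / 52
  s <- matrix(0, 8, 6)
  expect_error(raw_sensor_stream("LA", rev(t), s), "increasing")
  expect_error(raw_sensor_stream("LA", t[1:6], s[1:6, ]), "packets")
  expect_error(raw_sensor_stream("LA", numeric(0), s[0, , drop = FALSE]),
               "empty")
  expect_error(interpolate_to_uniform(raw_sensor_stream("LA", t[1:4],
                                                        s[1:4, ])),
               "2 packets")
})

test_that("gyro bias estimator matches the exhaustive window scan", {
  # constant channel
  expect_equal(estimate_gyro_bias(rep(1.7, 100)), 1.7)
  # an exactly-constant run inside noise wins (zero variance)
  set.seed(2)
  x <- rnorm(300, 5, 2)
  x[101:164] <- 3.3
  expect_equal(estimate_gyro_bias(x), 3.3)
  # random channels: exhaustive oracle over all start positions
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(400) + sin((1:400) / 20)
    expect_equal(estimate_gyro_bias(x), naive_gyro_bias(x), tolerance = 1e-10)
  }
  expect_error(estimate_gyro_bias(rnorm(63)), "shorter")
})

test_that("bias removal is idempotent when a zero-variance window exists", {
  set.seed(3)
  x <- rnorm(300, 2, 1)
  x[51:120] <- 4.2
  x1 <- x - estimate_gyro_bias(x)
  expect_equal(estimate_gyro_bias(x1), 0, tolerance = 1e-12)
})

test_that("median filter matches the naive sliding-sort oracle", {
  expect_equal(median_filter_channel(rep(2, 30)), rep(2, 30))
  # single spike removed
  x <- rep(1, 21); x[11] <- 50
  expect_equal(median_filter_channel(x), rep(1, 21))
  # arbitrary vectors vs naive oracle, including the shrinking edges
  for (seed in 1:3) {
    set.seed(seed)
    x <- rnorm(20)
    expect_equal(median_filter_channel(x), naive_median_filter(x))
  }
  expect_error(median_filter_channel(rnorm(10), width = 4), "odd")
})

test_that("median filter preserves order under monotone transforms inside", {
  set.seed(4)
  x <- rnorm(50)
  f <- function(v) exp(v)  # strictly increasing
  interior <- 3:48
  expect_equal(median_filter_channel(f(x))[interior],
               f(median_filter_channel(x))[interior])
})

test_that("windowing counts frames and slices sample-exactly", {
  sig <- matrix(seq_len(24 * 600), 24, 600)
  expect_equal(dim(window_frames(sig[, 1:120]))[1], 1L)
  expect_equal(dim(window_frames(sig[, 1:180]))[1], 2L)
  fr <- window_frames(sig)
  expect_equal(dim(fr), c(9L, 24L, 120L))
  for (i in 1:9) {
    expect_equal(fr[i, , ], sig[, (60 * (i - 1) + 1):(60 * (i - 1) + 120)])
  }
  expect_warning(window_frames(sig[, 1:100]), "zero frames")
})

test_that("concatenating every other frame reproduces the recording prefix", {
  set.seed(5)
  sig <- matrix(rnorm(24 * 540), 24, 540)
  fr <- window_frames(sig)
  odd <- seq(1, dim(fr)[1], by = 2)
  rebuilt <- do.call(cbind, lapply(odd, function(i) fr[i, , ]))
  expect_equal(rebuilt, sig[, seq_len(ncol(rebuilt))])
})

test_that("frame timing arithmetic matches the 52 Hz / 60-hop convention", {
  expect_equal(frames_to_seconds(0), 0)
  expect_equal(round(frames_to_seconds(60), 1), 69.2)
  expect_equal(frames_to_seconds(1), 60 / 52)
  expect_error(frames_to_seconds(-1), "non-negative")
})

test_that("preprocessing removes a constant gyro offset", {
  # quiet gyro with constant offset: after preprocessing, the min-variance
  # 64-window of that channel has mean ~0
  st <- lapply(sensor_ids(), function(sid) {
    make_test_stream(sid, n = 400, seed = match(sid, sensor_ids()),
                     fun = function(t) 0.05 * sin(2 * pi * 0.5 * t))
  })
  rec <- preprocess_recording(st)
  for (ch in imuhar:::gyro_rows()) {
    expect_lt(abs(estimate_gyro_bias(rec$signal[ch, ])), 0.02)
  }
  expect_equal(nrow(rec$signal), 24L)
  expect_error(preprocess_recording(st[1:3]), "four")
})

test_that("stream and label CSV round-trips are exact", {
  st <- make_test_stream(n = 32)
  path <- tempfile(fileext = ".csv")
  write_stream_csv(st, path)
  st2 <- read_stream_csv(path, "LA")
  expect_equal(st2$timestamps, st$timestamps)
  expect_equal(st2$samples, st$samples)

  labs <- factor(movement_classes()[c(1, 3, 3, 7, 2)],
                 levels = movement_classes())
  lpath <- tempfile(fileext = ".csv")
  write_labels_csv(labs, lpath)
  expect_equal(read_labels_csv(lpath), labs)

  soft <- matrix(runif(21), 3, 7)
  soft <- soft / rowSums(soft)
  write_labels_csv(soft, lpath)
  expect_equal(unname(read_labels_csv(lpath)), unname(soft),
               tolerance = 1e-12)
})

test_that("synthetic streams round-trip through write/read identically", {
  rec <- tiny_bundle()$recordings[[1]]
  path <- tempfile(fileext = ".csv")
  write_stream_csv(rec$streams$LL, path)
  st2 <- read_stream_csv(path, "LL")
  expect_equal(st2$timestamps, rec$streams$LL$timestamps)
  expect_equal(st2$samples, rec$streams$LL$samples)
})
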