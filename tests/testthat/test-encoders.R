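all_encoder_kinds <- c("dense", "conv1d", "conv2d_i", "conv2d_is", "conv2d_si")

test_that("every encoder kind emits the specified bottleneck dimensionality", {
  set.seed(1)
  frames <- array(rnorm(5 * 24 * 120), c(5, 24, 120))
  for (kind in all_encoder_kinds) {
    enc <- build_encoder(encoder_spec(kind))
    z <- encode(enc, frames)
    expect_equal(dim(z), c(5L, 160L), info = kind)
    expect_true(all(is.finite(z)), info = kind)
  }
  # reduced per-sensor bottleneck: 20 features x 4 sensors = 80 total
  enc80 <- build_encoder(encoder_spec("conv2d_si", per_sensor_dim = 20))
  expect_equal(ncol(encode(enc80, frames)), 80L)
  expect_error(encoder_spec("conv2d_si", bottleneck_dim = 150), "divisible")
  expect_error(encoder_spec("nope"), "arg")
})

test_that("single-frame and batched encoding agree, and repeats are identical", {
  set.seed(2)
  frames <- array(rnorm(4 * 24 * 120), c(4, 24, 120))
  for (kind in c("conv1d", "conv2d_si")) {
    enc <- build_encoder(encoder_spec(kind))
    zb <- encode(enc, frames)
    z1 <- encode(enc, frames[2, , ])
    expect_equal(z1[1, ], zb[2, ], tolerance = 1e-12, info = kind)
    expect_identical(encode(enc, frames), zb, info = kind)
  }
})

test_that("conv2d_si is equivariant to permuting the four sensor blocks", {
  set.seed(3)
  frames <- array(rnorm(3 * 24 * 120), c(3, 24, 120))
  enc <- build_encoder(encoder_spec("conv2d_si"))
  z <- encode(enc, frames)
  perm <- c(3L, 1L, 4L, 2L)
  fp <- frames
  for (s in 1:4) {
    fp[, imuhar:::sensor_rows(s), ] <- frames[, imuhar:::sensor_rows(perm[s]), ]
  }
  zp <- encode(enc, fp)
  D <- 40L
  for (s in 1:4) {
    expect_equal(zp[, ((s - 1) * D + 1):(s * D)],
                 z[, ((perm[s] - 1) * D + 1):(perm[s] * D)],
                 tolerance = 1e-12)
  }
  # equivariance survives a few training steps (holds for trained weights)
  ds <- tiny_dataset()[1]
  cfg <- train_config(max_epochs = 2, patience = 5, seed = 9,
                      minibatch = 40)
  m <- train_system(encoder_spec("conv2d_si"), temporal_spec("dense"),
                    ds, cfg = cfg)
  z <- encode(m$encoder, frames)
  zp <- encode(m$encoder, fp)
  for (s in 1:4) {
    expect_equal(zp[, ((s - 1) * D + 1):(s * D)],
                 z[, ((perm[s] - 1) * D + 1):(perm[s] * D)],
                 tolerance = 1e-10)
  }
})

test_that("conv2d_i accelerometer path ignores the gyroscope channels", {
  set.seed(4)
  enc <- build_encoder(encoder_spec("conv2d_i"))
  x1 <- array(rnorm(24 * 120 * 2), c(24, 120, 2))
  x2 <- x1
  x2[imuhar:::gyro_rows(), , ] <- rnorm(12 * 120 * 2)
  c1 <- imuhar:::nn_fwd(enc, x1)$cache
  c2 <- imuhar:::nn_fwd(enc, x2)$cache
  # pre-concatenation accelerometer-path activations are unchanged
  expect_identical(c1$pa$a2, c2$pa$a2)
  expect_false(identical(c1$pg$a2, c2$pg$a2))
})

test_that("zero input through zero-bias layers stays zero under LReLU/tanh", {
  set.seed(5)
  enc <- build_encoder(encoder_spec("conv1d"))
  for (mod in enc$modules) if (!is.null(mod$par$b)) mod$par$b[] <- 0
  z <- encode(enc, array(0, c(2, 24, 120)))
  expect_equal(unname(z), matrix(0, 2, 160))
})

test_that("parameter counts match a layer-by-layer closed-form ledger", {
  # single FC layer
  lin <- imuhar:::layer_linear(100, 10)
  expect_equal(sum(vapply(lin$par, length, numeric(1))), 100 * 10 + 10)
  # dense encoder at defaults: 2880-256-256-256-160 chain
  set.seed(6)
  enc <- build_encoder(encoder_spec("dense"))
  manual <- (2880 * 256 + 256) + (256 * 256 + 256) * 2 + (256 * 160 + 160)
  expect_equal(count_parameters(enc), manual)
  # conv1d: 4 conv layers (k = 5) + flatten FC
  enc1 <- build_encoder(encoder_spec("conv1d"))
  manual1 <- (24 * 5 * 64 + 64) + (64 * 5 * 64 + 64) + (64 * 5 * 96 + 96) +
    (96 * 5 * 96 + 96) + (96 * 8 * 160 + 160)
  expect_equal(count_parameters(enc1), manual1)
  # conv1d has fewer trainable parameters than dense
  expect_lt(count_parameters(enc1), count_parameters(enc))
})

test_that("conv2d_si parameter count is independent of sensor count (sharing)", {
  set.seed(7)
  enc <- build_encoder(encoder_spec("conv2d_si"))
  # every parameter belongs to the single shared submodule: summing over the
  # module list equals the count, with no per-sensor replication
  per_layer <- architecture_summary(enc)
  expect_equal(sum(per_layer$n_params), count_parameters(enc))
  # a one-sensor-per-frame forward and the 4-sensor forward use the same
  # modules; the count does not change after running on data
  frames <- array(rnorm(2 * 24 * 120), c(2, 24, 120))
  n0 <- count_parameters(enc)
  encode(enc, frames)
  expect_identical(count_parameters(enc), n0)
})

test_that("FLOP estimates match hand counts on small layers", {
  # FC 100 -> 10: 2 * 1000 MACs + 10 bias adds
  lin <- imuhar:::layer_linear(100, 10)
  imuhar:::reset_flops(lin)
  imuhar:::nn_fwd(lin, matrix(0, 100, 1))
  expect_equal(lin$flops, 2 * 100 * 10 + 10)
  expect_equal(lin$flops / 1e6, 0.00201)
  # 1-D conv: 2 k Cin Cout Tout + Cout Tout
  cv <- imuhar:::layer_conv1d(3, 4, k = 5, stride = 2)
  imuhar:::reset_flops(cv)
  out <- imuhar:::nn_fwd(cv, array(0, c(3, 20, 1)))
  t_out <- dim(out$y)[2]
  expect_equal(cv$flops, 2 * 5 * 3 * 4 * t_out + 4 * t_out)
  # encoder-level estimates are positive and finite
  for (kind in all_encoder_kinds) {
    expect_gt(estimate_flops(encoder_spec(kind)), 0)
  }
  # conv2d_si per-sensor cost is a quarter of the total
  sp <- encoder_spec("conv2d_si")
  expect_equal(estimate_flops(sp, per_sensor = TRUE) * 4,
               estimate_flops(sp, per_sensor = FALSE), tolerance = 1e-9)
})

test_that("doubling hidden widths roughly quadruples FC parameter counts", {
  set.seed(8)
  e1 <- build_encoder(encoder_spec("dense", dense_hidden = c(64, 64, 64)))
  e2 <- build_encoder(encoder_spec("dense", dense_hidden = c(128, 128, 128)))
  # interior FC layers scale ~4x; the whole count is dominated by the first
  # layer (2880 x h) which scales 2x, so check the pure h x h layer directly
  p1 <- architecture_summary(e1)
  p2 <- architecture_summary(e2)
  ratio <- p2$n_params[p2$layer == "fc2"] / p1$n_params[p1$layer == "fc2"]
  expect_gt(ratio, 3.8)
  expect_lt(ratio, 4.2)
})

test_that("encoder and temporal gradients match finite differences", {
  # one compact configuration per family keeps this fast while covering all
  # backward-pass code paths end-to-end
  set.seed(9)
  specs <- list(
    encoder_spec("dense", bottleneck_dim = 6, dense_hidden = c(8, 8, 8)),
    encoder_spec("conv1d", bottleneck_dim = 6, conv1d_channels = c(3, 3, 4, 4)),
    encoder_spec("conv2d_is", bottleneck_dim = 6, path_channels = 2,
                 fc_hidden = 8),
    encoder_spec("conv2d_si", per_sensor_dim = 2, si_path_channels = 2,
                 si_fc_hidden = 6)
  )
  for (sp in specs) {
    enc <- build_encoder(sp)
    xdim <- c(24, 120, 2)
    x <- array(rnorm(prod(xdim)), xdim)
    fc <- imuhar:::nn_fwd(enc, x)
    w <- array(rnorm(length(fc$y)), dim(fc$y))
    imuhar:::zero_grads(enc)
    gx <- imuhar:::nn_bwd(enc, fc$cache, w)
    probe <- sample(length(x), 12)
    ng <- vapply(probe, function(i) {
      eps <- 1e-6
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      (sum(imuhar:::nn_fwd(enc, xp)$y * w) -
         sum(imuhar:::nn_fwd(enc, xm)$y * w)) / (2 * eps)
    }, numeric(1))
    expect_equal(as.vector(gx)[probe], ng, tolerance = 1e-5, info = sp$kind)
  }
})
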