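# Sensor encoder architectures. Every encoder maps a batch of (24, 120)
# frames to a per-frame bottleneck feature vector (160-dimensional at
# defaults). Internally batches are channel-major arrays (24, 120, B).
#
# The five kinds:
#   dense     flatten (2880) -> FC 256 (tanh) -> FC 256 -> FC 256 -> FC D
#   conv1d    stacked 1-D convolutions (k = 5, stride 2) over time, all 24
#             channels fully connected into the filter channels; flatten + FC
#   conv2d_i  separate accelerometer and gyroscope paths; layer 1 fuses each
#             sensor's xyz triad (3x5 kernel, stride 3x2), layer 2 fuses the
#             four sensor-level rows of the modality (4x5 kernel, stride 1x2);
#             paths concatenated, two post-fusion 1-D convs, two FC layers
#   conv2d_is conv2d_i plus a shared path whose filters are applied to both
#             the accelerometer and the gyroscope stack
#   conv2d_si one shared per-sensor submodule (acc / gyro / shared paths, no
#             intersensor mixing anywhere) applied to each of the four sensors
#             with identical weights; per-sensor outputs concatenated

#' Encoder architecture specification
#'
#' @param kind One of `"dense"`, `"conv1d"`, `"conv2d_i"`, `"conv2d_is"`,
#'   `"conv2d_si"`.
#' @param bottleneck_dim Total bottleneck features per frame (default 160).
#'   For `conv2d_si` this must be divisible by 4.
#' @param per_sensor_dim Bottleneck features per sensor for `conv2d_si`
#'   (default `bottleneck_dim / 4`; the usual sweep is 40, 20, 10).
#' @param dense_hidden Hidden widths of the dense encoder.
#' @param conv1d_channels Filter channels of the four 1-D conv layers.
#' @param path_channels Filter channels of each 2-D fusion path.
#' @param fc_hidden Width of the post-fusion fully connected mixing layer.
#' @param si_path_channels,si_fc_hidden Same, for the shared per-sensor
#'   submodule of `conv2d_si`.
#' @param lrelu_slope Negative slope of the leaky ReLU activations.
#' @return An object of class `encoder_spec`.
#' @export
encoder_spec <- function(kind = c("dense", "conv1d", "conv2d_i", "conv2d_is",
                                  "conv2d_si"),
                         bottleneck_dim = 160L,
                         per_sensor_dim = NULL,
                         dense_hidden = c(256L, 256L, 256L),
                         conv1d_channels = c(64L, 64L, 96L, 96L),
                         path_channels = 32L,
                         fc_hidden = 256L,
                         si_path_channels = 16L,
                         si_fc_hidden = 128L,
                         lrelu_slope = 0.01) {
  kind <- match.arg(kind)
  bottleneck_dim <- as.integer(bottleneck_dim)
  if (kind == "conv2d_si") {
    if (is.null(per_sensor_dim)) {
      if (bottleneck_dim %% 4L != 0L) {
        stop("conv2d_si requires bottleneck_dim divisible by 4")
      }
      per_sensor_dim <- bottleneck_dim %/% 4L
    } else {
      per_sensor_dim <- as.integer(per_sensor_dim)
      bottleneck_dim <- 4L * per_sensor_dim
    }
  }
  structure(list(kind = kind, bottleneck_dim = bottleneck_dim,
                 per_sensor_dim = per_sensor_dim,
                 dense_hidden = as.integer(dense_hidden),
                 conv1d_channels = as.integer(conv1d_channels),
                 path_channels = as.integer(path_channels),
                 fc_hidden = as.integer(fc_hidden),
                 si_path_channels = as.integer(si_path_channels),
                 si_fc_hidden = as.integer(si_fc_hidden),
                 lrelu_slope = lrelu_slope,
                 n_channels = 24L, frame_len = 120L),
            class = "encoder_spec")
}

#' Build an encoder model
#'
#' Constructs a trainable encoder from its specification. Weights are
#' initialized from the current R random number generator state (uniform
#' fan-in scaling), so call `set.seed()` first for reproducible builds.
#'
#' @param spec An [encoder_spec()].
#' @return A model object usable with [encode()], [count_parameters()] and
#'   the training harness.
#' @export
build_encoder <- function(spec) {
  stopifnot(inherits(spec, "encoder_spec"))
  switch(spec$kind,
    dense = build_enc_dense(spec),
    conv1d = build_enc_conv1d(spec),
    conv2d_i = build_enc_conv2d(spec, shared_path = FALSE),
    conv2d_is = build_enc_conv2d(spec, shared_path = TRUE),
    conv2d_si = build_enc_conv2d_si(spec)
  )
}

## ---- dense ------------------------------------------------------------------

build_enc_dense <- function(spec) {
  d_in <- spec$n_channels * spec$frame_len
  widths <- c(d_in, spec$dense_hidden, spec$bottleneck_dim)
  mods <- list()
  for (i in seq_len(length(widths) - 1L)) {
    mods[[paste0("fc", i)]] <- layer_linear(widths[i], widths[i + 1L])
  }
  mods$tanh <- layer_act("tanh")
  new_model("enc_dense", mods, spec = spec, n_fc = length(widths) - 1L)
}

#' @exportS3Method
nn_fwd.enc_dense <- function(m, x, train = FALSE) {
  d <- dim(x)
  h <- matrix(x, d[1] * d[2], d[3])
  caches <- vector("list", m$n_fc)
  for (i in seq_len(m$n_fc)) {
    fc <- nn_fwd(m$modules[[paste0("fc", i)]], h, train)
    if (i < m$n_fc) {
      a <- nn_fwd(m$modules$tanh, fc$y, train)
      caches[[i]] <- list(fc = fc$cache, act = a$cache)
      h <- a$y
    } else {
      caches[[i]] <- list(fc = fc$cache)
      h <- fc$y
    }
  }
  list(y = h, cache = list(caches = caches, xdim = d))
}

#' @exportS3Method
nn_bwd.enc_dense <- function(m, cache, gy) {
  g <- gy
  for (i in rev(seq_len(m$n_fc))) {
    if (i < m$n_fc) g <- nn_bwd(m$modules$tanh, cache$caches[[i]]$act, g)
    g <- nn_bwd(m$modules[[paste0("fc", i)]], cache$caches[[i]]$fc, g)
  }
  array(g, cache$xdim)
}

## ---- 1-D CNN ----------------------------------------------------------------

build_enc_conv1d <- function(spec) {
  ch <- c(spec$n_channels, spec$conv1d_channels)
  mods <- list()
  for (i in seq_len(length(ch) - 1L)) {
    mods[[paste0("conv", i)]] <- layer_conv1d(ch[i], ch[i + 1L], k = 5L,
                                              stride = 2L)
  }
  t_out <- spec$frame_len
  for (i in seq_len(length(ch) - 1L)) t_out <- as.integer(ceiling(t_out / 2))
  mods$fc <- layer_linear(ch[length(ch)] * t_out, spec$bottleneck_dim)
  mods$act <- layer_act("lrelu", spec$lrelu_slope)
  new_model("enc_conv1d", mods, spec = spec, n_conv = length(ch) - 1L,
            flat_dim = ch[length(ch)] * t_out)
}

#' @exportS3Method
nn_fwd.enc_conv1d <- function(m, x, train = FALSE) {
  caches <- vector("list", m$n_conv)
  h <- x
  for (i in seq_len(m$n_conv)) {
    cv <- nn_fwd(m$modules[[paste0("conv", i)]], h, train)
    a <- nn_fwd(m$modules$act, cv$y, train)
    caches[[i]] <- list(conv = cv$cache, act = a$cache)
    h <- a$y
  }
  hdim <- dim(h)
  flat <- matrix(h, m$flat_dim, hdim[3])
  fc <- nn_fwd(m$modules$fc, flat, train)
  list(y = fc$y, cache = list(caches = caches, fc = fc$cache, hdim = hdim))
}

#' @exportS3Method
nn_bwd.enc_conv1d <- function(m, cache, gy) {
  g <- nn_bwd(m$modules$fc, cache$fc, gy)
  g <- array(g, cache$hdim)
  for (i in rev(seq_len(m$n_conv))) {
    g <- nn_bwd(m$modules$act, cache$caches[[i]]$act, g)
    g <- nn_bwd(m$modules[[paste0("conv", i)]], cache$caches[[i]]$conv, g)
  }
  g
}

## ---- 2-D CNN, individual (+ shared) paths -----------------------------------
# Modality stacks: the 12 accelerometer rows (sensor-major, xyz within sensor)
# form a (1, 12, 120) image, likewise for the gyroscope. A path is
#   conv2d(1 -> C, 3x5, stride 3x2)   xyz fusion -> 4 sensor rows
#   conv2d(C -> C, 4x5, stride 1x2)   sensor fusion -> 1 row
# each followed by LReLU. The shared path applies one set of filters to both
# modality stacks. Concatenated path channels feed two 1-D convs and two FCs.

build_enc_conv2d <- function(spec, shared_path) {
  C <- spec$path_channels
  mods <- list(
    acc1 = layer_conv2d(1L, C, 3L, 5L, 3L, 2L),
    acc2 = layer_conv2d(C, C, 4L, 5L, 1L, 2L),
    gyr1 = layer_conv2d(1L, C, 3L, 5L, 3L, 2L),
    gyr2 = layer_conv2d(C, C, 4L, 5L, 1L, 2L)
  )
  n_paths <- 2L
  if (shared_path) {
    mods$sh1 <- layer_conv2d(1L, C, 3L, 5L, 3L, 2L)
    mods$sh2 <- layer_conv2d(C, C, 4L, 5L, 1L, 2L)
    n_paths <- 4L
  }
  cat_ch <- n_paths * C
  mods$mix1 <- layer_conv1d(cat_ch, 32L, 5L, 2L)
  mods$mix2 <- layer_conv1d(32L, 32L, 5L, 2L)
  t_cat <- as.integer(ceiling(ceiling(spec$frame_len / 2) / 2))   # 30
  t_flat <- as.integer(ceiling(ceiling(t_cat / 2) / 2))           # 8
  mods$fc1 <- layer_linear(32L * t_flat, spec$fc_hidden)
  mods$fc2 <- layer_linear(spec$fc_hidden, spec$bottleneck_dim)
  mods$act <- layer_act("lrelu", spec$lrelu_slope)
  new_model("enc_conv2d", mods, spec = spec, shared_path = shared_path,
            cat_ch = cat_ch, flat_dim = 32L * t_flat)
}

# run one 2-layer 2-D path; returns (C, t, B) plus caches
conv2d_path_fwd <- function(l1, l2, act, x, train) {
  c1 <- nn_fwd(l1, x, train); a1 <- nn_fwd(act, c1$y, train)
  c2 <- nn_fwd(l2, a1$y, train); a2 <- nn_fwd(act, c2$y, train)
  y <- a2$y
  d <- dim(y)                                  # (C, 1, t, B)
  dim(y) <- c(d[1], d[3], d[4])
  list(y = y, cache = list(c1 = c1$cache, a1 = a1$cache, c2 = c2$cache,
                           a2 = a2$cache, ydim = d))
}

conv2d_path_bwd <- function(l1, l2, act, cache, gy) {
  g <- array(gy, cache$ydim)
  g <- nn_bwd(act, cache$a2, g)
  g <- nn_bwd(l2, cache$c2, g)
  g <- nn_bwd(act, cache$a1, g)
  nn_bwd(l1, cache$c1, g)
}

# modality stacks as (1, 12, 120, B) arrays
split_modalities <- function(x) {
  d <- dim(x)
  xa <- x[acc_rows(), , , drop = FALSE]
  xg <- x[gyro_rows(), , , drop = FALSE]
  dim(xa) <- c(1L, 12L, d[2], d[3])
  dim(xg) <- c(1L, 12L, d[2], d[3])
  list(xa = xa, xg = xg)
}

#' @exportS3Method
nn_fwd.enc_conv2d <- function(m, x, train = FALSE) {
  d <- dim(x)
  B <- d[3]
  sm <- split_modalities(x)
  act <- m$modules$act
  pa <- conv2d_path_fwd(m$modules$acc1, m$modules$acc2, act, sm$xa, train)
  pg <- conv2d_path_fwd(m$modules$gyr1, m$modules$gyr2, act, sm$xg, train)
  parts <- list(pa$y, pg$y)
  caches <- list(pa = pa$cache, pg = pg$cache)
  if (m$shared_path) {
    psa <- conv2d_path_fwd(m$modules$sh1, m$modules$sh2, act, sm$xa, train)
    psg <- conv2d_path_fwd(m$modules$sh1, m$modules$sh2, act, sm$xg, train)
    parts <- c(parts, list(psa$y, psg$y))
    caches$psa <- psa$cache
    caches$psg <- psg$cache
  }
  C <- dim(parts[[1]])[1]
  t_cat <- dim(parts[[1]])[2]
  hcat <- array(0, c(m$cat_ch, t_cat, B))
  for (i in seq_along(parts)) hcat[((i - 1L) * C + 1L):(i * C), , ] <- parts[[i]]
  m1 <- nn_fwd(m$modules$mix1, hcat, train)
  am1 <- nn_fwd(act, m1$y, train)
  m2 <- nn_fwd(m$modules$mix2, am1$y, train)
  am2 <- nn_fwd(act, m2$y, train)
  hdim <- dim(am2$y)
  flat <- matrix(am2$y, m$flat_dim, B)
  f1 <- nn_fwd(m$modules$fc1, flat, train)
  af1 <- nn_fwd(act, f1$y, train)
  f2 <- nn_fwd(m$modules$fc2, af1$y, train)
  caches <- c(caches, list(m1 = m1$cache, am1 = am1$cache, m2 = m2$cache,
                           am2 = am2$cache, f1 = f1$cache, af1 = af1$cache,
                           f2 = f2$cache, hdim = hdim, xdim = d, C = C,
                           t_cat = t_cat))
  list(y = f2$y, cache = caches)
}

#' @exportS3Method
nn_bwd.enc_conv2d <- function(m, cache, gy) {
  act <- m$modules$act
  g <- nn_bwd(m$modules$fc2, cache$f2, gy)
  g <- nn_bwd(act, cache$af1, g)
  g <- nn_bwd(m$modules$fc1, cache$f1, g)
  g <- array(g, cache$hdim)
  g <- nn_bwd(act, cache$am2, g)
  g <- nn_bwd(m$modules$mix2, cache$m2, g)
  g <- nn_bwd(act, cache$am1, g)
  g <- nn_bwd(m$modules$mix1, cache$m1, g)
  C <- cache$C
  ga <- conv2d_path_bwd(m$modules$acc1, m$modules$acc2, act, cache$pa,
                        g[1:C, , , drop = FALSE])
  gg <- conv2d_path_bwd(m$modules$gyr1, m$modules$gyr2, act, cache$pg,
                        g[(C + 1L):(2L * C), , , drop = FALSE])
  if (m$shared_path) {
    gsa <- conv2d_path_bwd(m$modules$sh1, m$modules$sh2, act, cache$psa,
                           g[(2L * C + 1L):(3L * C), , , drop = FALSE])
    gsg <- conv2d_path_bwd(m$modules$sh1, m$modules$sh2, act, cache$psg,
                           g[(3L * C + 1L):(4L * C), , , drop = FALSE])
    ga <- ga + gsa
    gg <- gg + gsg
  }
  gx <- array(0, cache$xdim)
  dim(ga) <- c(12L, cache$xdim[2], cache$xdim[3])
  dim(gg) <- c(12L, cache$xdim[2], cache$xdim[3])
  gx[acc_rows(), , ] <- ga
  gx[gyro_rows(), , ] <- gg
  gx
}

## ---- 2-D CNN, sensor-independent module -------------------------------------
# One submodule, shared across all four sensors, maps a sensor's (6, 120)
# channels to per_sensor_dim features: acc path, gyro path and a shared path
# (applied to both triads) of (3x5, stride 3x2) xyz-fusion convs; the
# concatenated path channels feed two 1-D convs and two FCs. No layer mixes
# channels across sensors, so permuting sensors permutes the output blocks.

build_enc_conv2d_si <- function(spec) {
  C <- spec$si_path_channels
  mods <- list(
    pacc = layer_conv2d(1L, C, 3L, 5L, 3L, 2L),
    pgyr = layer_conv2d(1L, C, 3L, 5L, 3L, 2L),
    psh = layer_conv2d(1L, C, 3L, 5L, 3L, 2L)
  )
  cat_ch <- 4L * C
  mods$mix1 <- layer_conv1d(cat_ch, 32L, 5L, 2L)
  mods$mix2 <- layer_conv1d(32L, 32L, 5L, 2L)
  t1 <- as.integer(ceiling(spec$frame_len / 2))   # 60
  t_flat <- as.integer(ceiling(ceiling(t1 / 2) / 2))  # 15
  mods$fc1 <- layer_linear(32L * t_flat, spec$si_fc_hidden)
  mods$fc2 <- layer_linear(spec$si_fc_hidden, spec$per_sensor_dim)
  mods$act <- layer_act("lrelu", spec$lrelu_slope)
  new_model("enc_conv2d_si", mods, spec = spec, cat_ch = cat_ch,
            flat_dim = 32L * t_flat)
}

si_sensor_fwd <- function(m, xs, train) {
  # xs: (6, 120, B) one sensor
  d <- dim(xs)
  B <- d[3]
  xa <- xs[1:3, , , drop = FALSE]
  xg <- xs[4:6, , , drop = FALSE]
  dim(xa) <- c(1L, 3L, d[2], B)
  dim(xg) <- c(1L, 3L, d[2], B)
  act <- m$modules$act
  one_path <- function(layer, x) {
    cv <- nn_fwd(layer, x, train)
    a <- nn_fwd(act, cv$y, train)
    y <- a$y
    yd <- dim(y)
    dim(y) <- c(yd[1], yd[3], yd[4])
    list(y = y, cache = list(cv = cv$cache, a = a$cache, ydim = yd))
  }
  pa <- one_path(m$modules$pacc, xa)
  pg <- one_path(m$modules$pgyr, xg)
  sa <- one_path(m$modules$psh, xa)
  sg <- one_path(m$modules$psh, xg)
  C <- dim(pa$y)[1]
  t1 <- dim(pa$y)[2]
  hcat <- array(0, c(m$cat_ch, t1, B))
  hcat[1:C, , ] <- pa$y
  hcat[(C + 1L):(2L * C), , ] <- pg$y
  hcat[(2L * C + 1L):(3L * C), , ] <- sa$y
  hcat[(3L * C + 1L):(4L * C), , ] <- sg$y
  m1 <- nn_fwd(m$modules$mix1, hcat, train)
  a1 <- nn_fwd(act, m1$y, train)
  m2 <- nn_fwd(m$modules$mix2, a1$y, train)
  a2 <- nn_fwd(act, m2$y, train)
  hdim <- dim(a2$y)
  flat <- matrix(a2$y, m$flat_dim, B)
  f1 <- nn_fwd(m$modules$fc1, flat, train)
  af1 <- nn_fwd(act, f1$y, train)
  f2 <- nn_fwd(m$modules$fc2, af1$y, train)
  list(y = f2$y,
       cache = list(pa = pa$cache, pg = pg$cache, sa = sa$cache,
                    sg = sg$cache, m1 = m1$cache, a1 = a1$cache,
                    m2 = m2$cache, a2 = a2$cache, f1 = f1$cache,
                    af1 = af1$cache, f2 = f2$cache, hdim = hdim,
                    C = C, xdim = d))
}

si_sensor_bwd <- function(m, cache, gy) {
  act <- m$modules$act
  g <- nn_bwd(m$modules$fc2, cache$f2, gy)
  g <- nn_bwd(act, cache$af1, g)
  g <- nn_bwd(m$modules$fc1, cache$f1, g)
  g <- array(g, cache$hdim)
  g <- nn_bwd(act, cache$a2, g)
  g <- nn_bwd(m$modules$mix2, cache$m2, g)
  g <- nn_bwd(act, cache$a1, g)
  g <- nn_bwd(m$modules$mix1, cache$m1, g)
  C <- cache$C
  path_bwd <- function(layer, pc, gpart) {
    gp <- array(gpart, pc$ydim)
    gp <- nn_bwd(act, pc$a, gp)
    nn_bwd(layer, pc$cv, gp)
  }
  ga <- path_bwd(m$modules$pacc, cache$pa, g[1:C, , , drop = FALSE])
  gg <- path_bwd(m$modules$pgyr, cache$pg, g[(C + 1L):(2L * C), , , drop = FALSE])
  gsa <- path_bwd(m$modules$psh, cache$sa, g[(2L * C + 1L):(3L * C), , , drop = FALSE])
  gsg <- path_bwd(m$modules$psh, cache$sg, g[(3L * C + 1L):(4L * C), , , drop = FALSE])
  ga <- ga + gsa
  gg <- gg + gsg
  gs <- array(0, cache$xdim)
  dim(ga) <- c(3L, cache$xdim[2], cache$xdim[3])
  dim(gg) <- c(3L, cache$xdim[2], cache$xdim[3])
  gs[1:3, , ] <- ga
  gs[4:6, , ] <- gg
  gs
}

#' @exportS3Method
nn_fwd.enc_conv2d_si <- function(m, x, train = FALSE) {
  # the submodule is weight-shared across sensors, so the four sensors are
  # stacked into the batch dimension and processed in a single pass
  d <- dim(x)
  B <- d[3]
  D <- m$spec$per_sensor_dim
  xs <- array(0, c(6L, d[2], 4L * B))
  for (s in 1:4) {
    xs[, , ((s - 1L) * B + 1L):(s * B)] <- x[sensor_rows(s), , , drop = FALSE]
  }
  fs <- si_sensor_fwd(m, xs, train)
  y <- matrix(0, 4L * D, B)
  for (s in 1:4) {
    y[((s - 1L) * D + 1L):(s * D), ] <-
      fs$y[, ((s - 1L) * B + 1L):(s * B), drop = FALSE]
  }
  list(y = y, cache = list(sensor = fs$cache, xdim = d))
}

#' @exportS3Method
nn_bwd.enc_conv2d_si <- function(m, cache, gy) {
  D <- m$spec$per_sensor_dim
  d <- cache$xdim
  B <- d[3]
  gys <- matrix(0, D, 4L * B)
  for (s in 1:4) {
    gys[, ((s - 1L) * B + 1L):(s * B)] <-
      gy[((s - 1L) * D + 1L):(s * D), , drop = FALSE]
  }
  gs <- si_sensor_bwd(m, cache$sensor, gys)
  gx <- array(0, d)
  for (s in 1:4) {
    gx[sensor_rows(s), , ] <- gs[, , ((s - 1L) * B + 1L):(s * B), drop = FALSE]
  }
  gx
}

## ---- public inference -------------------------------------------------------

#' Encode frames into bottleneck features
#'
#' Deterministic inference pass of an encoder over a frame tensor.
#'
#' @param model A built encoder ([build_encoder()]).
#' @param frames Frame tensor of shape `(n_frames, 24, 120)`, or a single
#'   `(24, 120)` frame.
#' @return A `(n_frames, bottleneck_dim)` matrix of bottleneck features.
#' @export
encode <- function(model, frames) {
  stopifnot(inherits(model, "nn_model"))
  if (length(dim(frames)) == 2L) {
    frames <- array(frames, c(1L, dim(frames)))
  }
  d <- dim(frames)
  if (d[2] != model$spec$n_channels || d[3] != model$spec$frame_len) {
    stop("frame tensor must be (n_frames, ", model$spec$n_channels, ", ",
         model$spec$frame_len, ")")
  }
  x <- aperm(frames, c(2, 3, 1))
  t(nn_fwd(model, x, train = FALSE)$y)
}

#' Estimate inference cost in MFLOPs
#'
#' Counts floating point operations of one forward pass, with 2 FLOPs per
#' multiply-accumulate plus one per bias addition, summed over layers. For the
#' sensor-independent encoder (`conv2d_si`) the per-sensor cost (total / 4) is
#' reported by default, matching the view of the submodule as an embedded
#' per-sensor feature extractor.
#'
#' @param spec An [encoder_spec()] or [temporal_spec()].
#' @param per_sensor For `conv2d_si`: report per-sensor cost (default `TRUE`).
#' @return MFLOPs per frame (numeric).
#' @export
estimate_flops <- function(spec, per_sensor = TRUE) {
  if (inherits(spec, "encoder_spec")) {
    model <- build_encoder(spec)
    reset_flops(model)
    x <- array(0, c(spec$n_channels, spec$frame_len, 1L))
    nn_fwd(model, x, train = FALSE)
    fl <- total_flops(model)
    if (spec$kind == "conv2d_si" && per_sensor) fl <- fl / 4
    return(fl / 1e6)
  }
  if (inherits(spec, "temporal_spec")) {
    model <- build_temporal(spec)
    reset_flops(model)
    T <- 64L
    nn_fwd(model, matrix(0, spec$d_in, T), train = FALSE)
    return(total_flops(model) / T / 1e6)
  }
  stop("spec must be an encoder_spec or temporal_spec")
}

#' Per-layer architecture summary
#'
#' @param model A built model.
#' @return A data.frame with one row per primitive layer (name, class,
#'   parameter count).
#' @export
architecture_summary <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  data.frame(
    layer = names(model$modules),
    class = vapply(model$modules, function(m) class(m)[1], character(1)),
    n_params = vapply(model$modules, function(m) {
      sum(vapply(m$par, length, numeric(1)))
    }, numeric(1)),
    row.names = NULL
  )
}
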