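# Time-series modeling modules. Each maps a bottleneck sequence (D, T) to
# per-frame class logits (K, T); softmax is applied at prediction time.
#
#   dense    frame-wise FC(hidden, LReLU) -> FC(K); no temporal modeling
#   lstm     unidirectional LSTM(hidden) -> FC(K); causal
#   gru      unidirectional GRU(hidden)  -> FC(K); causal
#   bgru     forward GRU + backward GRU, outputs concatenated -> FC(K)
#   wavenet  1x1 input projection, then stacked gated dilated convolution
#            blocks (tanh(filter) * sigmoid(gate), 1x1 residual and skip
#            projections); skip sum -> LReLU -> 1x1 -> LReLU -> 1x1 -> K.
#            Convolutions are centered by default (offline classification);
#            `causal = TRUE` switches to left-padded convolutions.

#' Temporal model specification
#'
#' @param kind One of `"dense"`, `"lstm"`, `"gru"`, `"bgru"`, `"wavenet"`.
#' @param d_in Input (bottleneck) dimensionality, default 160.
#' @param hidden_dim Hidden width (recurrent state size / dense hidden layer),
#'   default 160.
#' @param n_classes Number of output classes, default 7.
#' @param dilations Dilation of each WaveNet block, default `c(1, 2, 4, 8)`.
#' @param kernel WaveNet filter size, default 5 (odd, for centered mode).
#' @param channels WaveNet residual/skip channel width, default 64.
#' @param causal Use causal (left-padded) WaveNet convolutions instead of
#'   centered ones.
#' @param lrelu_slope Negative slope of leaky ReLU activations.
#' @return An object of class `temporal_spec`.
#' @export
temporal_spec <- function(kind = c("dense", "lstm", "gru", "bgru", "wavenet"),
                          d_in = 160L, hidden_dim = 160L, n_classes = 7L,
                          dilations = c(1L, 2L, 4L, 8L), kernel = 5L,
                          channels = 64L, causal = FALSE,
                          lrelu_slope = 0.01) {
  kind <- match.arg(kind)
  dilations <- as.integer(dilations)
  if (any(dilations <= 0L) || is.unsorted(dilations, strictly = TRUE)) {
    stop("dilations must be positive and increasing")
  }
  if (!causal && kernel %% 2L == 0L) {
    stop("kernel must be odd for centered convolutions")
  }
  structure(list(kind = kind, d_in = as.integer(d_in),
                 hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes),
                 dilations = dilations, kernel = as.integer(kernel),
                 channels = as.integer(channels), causal = causal,
                 lrelu_slope = lrelu_slope),
            class = "temporal_spec")
}

#' Build a temporal model
#'
#' Constructs a trainable time-series module from its specification. Weights
#' come from the current RNG state; `set.seed()` first for reproducibility.
#'
#' @param spec A [temporal_spec()].
#' @return A model object usable with [predict_sequence()] and the training
#'   harness.
#' @export
build_temporal <- function(spec) {
  stopifnot(inherits(spec, "temporal_spec"))
  switch(spec$kind,
    dense = {
      mods <- list(fc1 = layer_linear(spec$d_in, spec$hidden_dim),
                   fc2 = layer_linear(spec$hidden_dim, spec$n_classes),
                   act = layer_act("lrelu", spec$lrelu_slope))
      new_model("tmp_dense", mods, spec = spec)
    },
    lstm = {
      mods <- list(rec = layer_lstm(spec$d_in, spec$hidden_dim),
                   out = layer_linear(spec$hidden_dim, spec$n_classes))
      new_model("tmp_rnn", mods, spec = spec)
    },
    gru = {
      mods <- list(rec = layer_gru(spec$d_in, spec$hidden_dim),
                   out = layer_linear(spec$hidden_dim, spec$n_classes))
      new_model("tmp_rnn", mods, spec = spec)
    },
    bgru = {
      mods <- list(fwd = layer_gru(spec$d_in, spec$hidden_dim),
                   bwd = layer_gru(spec$d_in, spec$hidden_dim),
                   out = layer_linear(2L * spec$hidden_dim, spec$n_classes))
      new_model("tmp_bgru", mods, spec = spec)
    },
    wavenet = build_tmp_wavenet(spec)
  )
}

#' @exportS3Method
nn_fwd.tmp_dense <- function(m, x, train = FALSE) {
  f1 <- nn_fwd(m$modules$fc1, x, train)
  a <- nn_fwd(m$modules$act, f1$y, train)
  f2 <- nn_fwd(m$modules$fc2, a$y, train)
  list(y = f2$y, cache = list(f1 = f1$cache, a = a$cache, f2 = f2$cache))
}

#' @exportS3Method
nn_bwd.tmp_dense <- function(m, cache, gy) {
  g <- nn_bwd(m$modules$fc2, cache$f2, gy)
  g <- nn_bwd(m$modules$act, cache$a, g)
  nn_bwd(m$modules$fc1, cache$f1, g)
}

#' @exportS3Method
nn_fwd.tmp_rnn <- function(m, x, train = FALSE) {
  r <- nn_fwd(m$modules$rec, x, train)
  o <- nn_fwd(m$modules$out, r$y, train)
  list(y = o$y, cache = list(rec = r$cache, out = o$cache))
}

#' @exportS3Method
nn_bwd.tmp_rnn <- function(m, cache, gy) {
  g <- nn_bwd(m$modules$out, cache$out, gy)
  nn_bwd(m$modules$rec, cache$rec, g)
}

#' @exportS3Method
nn_fwd.tmp_bgru <- function(m, x, train = FALSE) {
  T <- ncol(x)
  rev_idx <- rev(seq_len(T))
  f <- nn_fwd(m$modules$fwd, x, train)
  b <- nn_fwd(m$modules$bwd, x[, rev_idx, drop = FALSE], train)
  h <- rbind(f$y, b$y[, rev_idx, drop = FALSE])
  o <- nn_fwd(m$modules$out, h, train)
  list(y = o$y, cache = list(f = f$cache, b = b$cache, out = o$cache, T = T))
}

#' @exportS3Method
nn_bwd.tmp_bgru <- function(m, cache, gy) {
  H <- m$spec$hidden_dim
  rev_idx <- rev(seq_len(cache$T))
  gh <- nn_bwd(m$modules$out, cache$out, gy)
  gf <- nn_bwd(m$modules$fwd, cache$f, gh[1:H, , drop = FALSE])
  gb <- nn_bwd(m$modules$bwd, cache$b,
               gh[(H + 1L):(2L * H), rev_idx, drop = FALSE])
  gf + gb[, rev_idx, drop = FALSE]
}

## ---- WaveNet ----------------------------------------------------------------

build_tmp_wavenet <- function(spec) {
  ch <- spec$channels
  pad <- if (spec$causal) "causal" else "centered"
  mods <- list(conv_in = layer_conv1d(spec$d_in, ch, 1L))
  for (i in seq_along(spec$dilations)) {
    d <- spec$dilations[i]
    mods[[paste0("f", i)]] <- layer_conv1d(ch, ch, spec$kernel, 1L, d, pad)
    mods[[paste0("g", i)]] <- layer_conv1d(ch, ch, spec$kernel, 1L, d, pad)
    mods[[paste0("res", i)]] <- layer_conv1d(ch, ch, 1L)
    mods[[paste0("skip", i)]] <- layer_conv1d(ch, ch, 1L)
  }
  mods$head1 <- layer_conv1d(ch, ch, 1L)
  mods$head2 <- layer_conv1d(ch, spec$n_classes, 1L)
  mods$act <- layer_act("lrelu", spec$lrelu_slope)
  new_model("tmp_wavenet", mods, spec = spec,
            n_blocks = length(spec$dilations))
}

#' @exportS3Method
nn_fwd.tmp_wavenet <- function(m, x, train = FALSE) {
  T <- ncol(x)
  x3 <- array(x, c(nrow(x), T, 1L))
  cin <- nn_fwd(m$modules$conv_in, x3, train)
  h <- cin$y
  skips <- 0
  blocks <- vector("list", m$n_blocks)
  for (i in seq_len(m$n_blocks)) {
    f <- nn_fwd(m$modules[[paste0("f", i)]], h, train)
    g <- nn_fwd(m$modules[[paste0("g", i)]], h, train)
    tf <- tanh(f$y)
    sg <- 1 / (1 + exp(-g$y))
    z <- tf * sg
    sk <- nn_fwd(m$modules[[paste0("skip", i)]], z, train)
    rs <- nn_fwd(m$modules[[paste0("res", i)]], z, train)
    blocks[[i]] <- list(f = f$cache, g = g$cache, tf = tf, sg = sg,
                        sk = sk$cache, rs = rs$cache)
    skips <- skips + sk$y
    h <- rs$y + h
  }
  a1 <- nn_fwd(m$modules$act, skips, train)
  h1 <- nn_fwd(m$modules$head1, a1$y, train)
  a2 <- nn_fwd(m$modules$act, h1$y, train)
  h2 <- nn_fwd(m$modules$head2, a2$y, train)
  y <- h2$y
  dim(y) <- c(dim(y)[1], T)
  list(y = y, cache = list(cin = cin$cache, blocks = blocks, a1 = a1$cache,
                           h1 = h1$cache, a2 = a2$cache, h2 = h2$cache,
                           T = T, d_in = nrow(x)))
}

#' @exportS3Method
nn_bwd.tmp_wavenet <- function(m, cache, gy) {
  T <- cache$T
  g <- array(gy, c(nrow(gy), T, 1L))
  g <- nn_bwd(m$modules$head2, cache$h2, g)
  g <- nn_bwd(m$modules$act, cache$a2, g)
  g <- nn_bwd(m$modules$head1, cache$h1, g)
  gskip <- nn_bwd(m$modules$act, cache$a1, g)
  gh <- 0
  for (i in rev(seq_len(m$n_blocks))) {
    bl <- cache$blocks[[i]]
    gz <- nn_bwd(m$modules[[paste0("skip", i)]], bl$sk, gskip)
    if (!identical(gh, 0)) {
      gz <- gz + nn_bwd(m$modules[[paste0("res", i)]], bl$rs, gh)
    } else {
      gh <- array(0, dim(gz))
    }
    gtf <- gz * bl$sg
    gsg <- gz * bl$tf
    gf <- gtf * (1 - bl$tf^2)
    gg <- gsg * bl$sg * (1 - bl$sg)
    gh <- gh + nn_bwd(m$modules[[paste0("f", i)]], bl$f, gf) +
      nn_bwd(m$modules[[paste0("g", i)]], bl$g, gg)
  }
  gx <- nn_bwd(m$modules$conv_in, cache$cin, gh)
  matrix(gx, cache$d_in, T)
}

## ---- public API ---------------------------------------------------------------

#' Receptive field of the WaveNet stack, in frames
#'
#' For stacked dilated convolutions with filter size k and dilations d_i the
#' receptive field is `1 + (k - 1) * sum(d)`. At the defaults (k = 5,
#' d = 1, 2, 4, 8) this is 61 frames; the span of 60 frame hops corresponds to
#' 69.2 s at the 52 Hz / 60-sample hop timing (see [frames_to_seconds()]).
#'
#' @param spec A [temporal_spec()] with `kind = "wavenet"`.
#' @return Integer receptive field in frames.
#' @export
receptive_field_frames <- function(spec) {
  stopifnot(inherits(spec, "temporal_spec"))
  if (spec$kind != "wavenet") {
    stop("receptive field is defined for the wavenet kind only")
  }
  1L + (spec$kernel - 1L) * sum(spec$dilations)
}

#' Run the full encoder + temporal pipeline on a frame tensor
#'
#' @param encoder A built encoder model.
#' @param temporal A built temporal model.
#' @param frames Frame tensor `(n_frames, 24, 120)`.
#' @return A `(n_frames, n_classes)` matrix of class probabilities (rows sum
#'   to 1), with class names as column names.
#' @export
predict_sequence <- function(encoder, temporal, frames) {
  z <- encode(encoder, frames)
  if (ncol(z) != temporal$spec$d_in) {
    stop("encoder bottleneck (", ncol(z), ") does not match temporal input (",
         temporal$spec$d_in, ")")
  }
  logits <- nn_fwd(temporal, t(z), train = FALSE)$y
  probs <- t(softmax_cols(logits))
  colnames(probs) <- movement_classes()[seq_len(ncol(probs))]
  probs
}
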