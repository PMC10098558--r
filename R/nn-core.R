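# Minimal neural-network engine: layer primitives with explicit forward /
# backward passes, parameter containers and an Adam optimizer. All data is
# feature-major with the batch in the LAST array dimension:
#   linear     x: (in, B)          conv1d  x: (C, T, B)
#   conv2d     x: (C, H, W, B)     sequences: (D, T) with B = 1 implied
# Forward calls return list(y, cache); backward takes the cache explicitly so
# that one module applied several times per step (weight sharing) keeps a
# cache per call and accumulates gradients across calls.

new_module <- function(cls, ...) {
  m <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  m$par <- list()
  m$gr <- list()
  m$flops <- 0
  class(m) <- c(cls, "nn_module")
  m
}

# uniform fan-in initialization: U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_weights <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

nn_fwd <- function(m, x, train = FALSE) UseMethod("nn_fwd")
nn_bwd <- function(m, cache, gy) UseMethod("nn_bwd")

## ---- linear ---------------------------------------------------------------

layer_linear <- function(d_in, d_out) {
  m <- new_module("nn_linear", d_in = d_in, d_out = d_out)
  m$par$W <- init_weights(d_out, d_in, d_in)
  m$par$b <- numeric(d_out)
  m$gr$W <- matrix(0, d_out, d_in)
  m$gr$b <- numeric(d_out)
  m
}

#' @exportS3Method
nn_fwd.nn_linear <- function(m, x, train = FALSE) {
  y <- m$par$W %*% x + m$par$b
  m$flops <- m$flops + (2 * m$d_in * m$d_out + m$d_out)
  list(y = y, cache = x)
}

#' @exportS3Method
nn_bwd.nn_linear <- function(m, cache, gy) {
  m$gr$W <- m$gr$W + tcrossprod(gy, cache)
  m$gr$b <- m$gr$b + rowSums(gy)
  crossprod(m$par$W, gy)
}

## ---- elementwise activations ----------------------------------------------

layer_act <- function(kind = c("lrelu", "tanh", "sigmoid"), slope = 0.01) {
  kind <- match.arg(kind)
  new_module("nn_act", kind = kind, slope = slope)
}

#' @exportS3Method
nn_fwd.nn_act <- function(m, x, train = FALSE) {
  y <- switch(m$kind,
    lrelu = x * (1 - (1 - m$slope) * (x < 0)),
    tanh = tanh(x),
    sigmoid = 1 / (1 + exp(-x))
  )
  list(y = y, cache = y)
}

#' @exportS3Method
nn_bwd.nn_act <- function(m, cache, gy) {
  switch(m$kind,
    lrelu = gy * (1 - (1 - m$slope) * (cache < 0)),
    tanh = gy * (1 - cache^2),
    sigmoid = gy * cache * (1 - cache)
  )
}

## ---- 1-D convolution --------------------------------------------------------
# x: (C_in, T, B). Padding modes: "same_ceil" (stride s halves length with
# ceiling), "centered" (stride-1 dilated, output length = input length),
# "causal" (all padding on the left), or an explicit c(left, right).

layer_conv1d <- function(c_in, c_out, k, stride = 1L, dilation = 1L,
                         pad = "same_ceil") {
  m <- new_module("nn_conv1d", c_in = c_in, c_out = c_out, k = as.integer(k),
                  stride = as.integer(stride), dilation = as.integer(dilation),
                  pad = pad, idx_cache = list())
  fan_in <- c_in * k
  m$par$W <- init_weights(c_out, fan_in, fan_in)
  m$par$b <- numeric(c_out)
  m$gr$W <- matrix(0, c_out, fan_in)
  m$gr$b <- numeric(c_out)
  m
}

conv1d_geometry <- function(m, T) {
  eff_k <- (m$k - 1L) * m$dilation + 1L
  if (is.numeric(m$pad)) {
    pl <- as.integer(m$pad[1]); pr <- as.integer(m$pad[2])
    t_out <- (T + pl + pr - eff_k) %/% m$stride + 1L
  } else if (m$pad == "same_ceil") {
    t_out <- as.integer(ceiling(T / m$stride))
    total <- max(0L, (t_out - 1L) * m$stride + eff_k - T)
    pl <- total %/% 2L; pr <- total - pl
  } else if (m$pad == "centered") {
    t_out <- as.integer(ceiling(T / m$stride))
    total <- max(0L, (t_out - 1L) * m$stride + eff_k - T)
    pl <- total %/% 2L; pr <- total - pl
  } else if (m$pad == "causal") {
    t_out <- as.integer(ceiling(T / m$stride))
    total <- max(0L, (t_out - 1L) * m$stride + eff_k - T)
    pl <- total; pr <- 0L
  } else stop("unknown padding mode: ", m$pad)
  list(pl = pl, pr = pr, t_out = t_out, eff_k = eff_k)
}

# linear gather indices into a (c_in, T_pad) plane; patch ordering is channel
# fastest, kernel tap second; columns are output positions
conv1d_index <- function(c_in, k, stride, dilation, t_out) {
  starts <- (seq_len(t_out) - 1L) * stride             # 0-based start times
  taps <- (seq_len(k) - 1L) * dilation                 # 0-based tap offsets
  tmat <- outer(taps, starts, "+")                     # (k, t_out) 0-based
  idx <- matrix(0L, c_in * k, t_out)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * c_in + 1L):(j * c_in)
    idx[rows, ] <- rep(tmat[j, ] * c_in, each = c_in) + seq_len(c_in)
  }
  idx
}

pad_time3 <- function(x, pl, pr) {
  if (pl == 0L && pr == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + pl + pr, d[3]))
  xp[, (pl + 1L):(pl + d[2]), ] <- x
  xp
}

#' @exportS3Method
nn_fwd.nn_conv1d <- function(m, x, train = FALSE) {
  d <- dim(x)
  T <- d[2]; B <- d[3]
  g <- conv1d_geometry(m, T)
  xp <- pad_time3(x, g$pl, g$pr)
  t_pad <- dim(xp)[2]
  key <- paste0(T, ":", t_pad)
  idx <- m$idx_cache[[key]]
  if (is.null(idx)) {
    idx <- conv1d_index(m$c_in, m$k, m$stride, m$dilation, g$t_out)
    m$idx_cache[[key]] <- idx
  }
  patch <- m$c_in * m$k
  dim(xp) <- c(m$c_in * t_pad, B)
  xmat <- xp[as.vector(idx), , drop = FALSE]
  dim(xmat) <- c(patch, g$t_out * B)                  # (patch, t_out*B)
  Y <- m$par$W %*% xmat + m$par$b
  m$flops <- m$flops + (2 * patch * m$c_out + m$c_out) * g$t_out
  list(y = array(Y, c(m$c_out, g$t_out, B)),
       cache = list(xmat = xmat, idx = idx, T = T, t_pad = t_pad,
                    pl = g$pl, t_out = g$t_out, B = B))
}

#' @exportS3Method
nn_bwd.nn_conv1d <- function(m, cache, gy) {
  B <- cache$B
  G <- gy
  dim(G) <- c(m$c_out, cache$t_out * B)                # (c_out, t_out*B)
  m$gr$W <- m$gr$W + tcrossprod(G, cache$xmat)
  m$gr$b <- m$gr$b + rowSums(G)
  gxcol <- crossprod(m$par$W, G)                       # (patch, t_out*B)
  dim(gxcol) <- c(length(cache$idx), B)                # (patch*t_out, B)
  rs <- rowsum(gxcol, group = as.vector(cache$idx))
  gxp <- matrix(0, m$c_in * cache$t_pad, B)
  gxp[as.integer(rownames(rs)), ] <- rs
  gxp <- array(gxp, c(m$c_in, cache$t_pad, B))
  gxp[, (cache$pl + 1L):(cache$pl + cache$T), , drop = FALSE]
}

## ---- 2-D convolution --------------------------------------------------------
# x: (C_in, H, W, B). The height axis holds channels being fused (xyz triads or
# sensors) and is never padded; the width (time) axis uses "same_ceil" padding.

layer_conv2d <- function(c_in, c_out, kh, kw, sh = 1L, sw = 1L) {
  m <- new_module("nn_conv2d", c_in = c_in, c_out = c_out,
                  kh = as.integer(kh), kw = as.integer(kw),
                  sh = as.integer(sh), sw = as.integer(sw), idx_cache = list())
  fan_in <- c_in * kh * kw
  m$par$W <- init_weights(c_out, fan_in, fan_in)
  m$par$b <- numeric(c_out)
  m$gr$W <- matrix(0, c_out, fan_in)
  m$gr$b <- numeric(c_out)
  m
}

conv2d_index <- function(c_in, H, w_pad, kh, kw, sh, sw, h_out, w_out) {
  patch <- c_in * kh * kw
  idx <- matrix(0L, patch, h_out * w_out)
  pos <- 0L
  hw_starts_h <- (seq_len(h_out) - 1L) * sh
  hw_starts_w <- (seq_len(w_out) - 1L) * sw
  base_chan <- seq_len(c_in)
  for (b in seq_len(w_out)) {
    w0 <- hw_starts_w[b]
    for (a in seq_len(h_out)) {
      h0 <- hw_starts_h[a]
      pos <- pos + 1L
      p <- 0L
      for (jw in 0:(kw - 1L)) {
        for (jh in 0:(kh - 1L)) {
          lin <- (h0 + jh) * c_in + (w0 + jw) * c_in * H
          idx[(p + 1L):(p + c_in), pos] <- lin + base_chan
          p <- p + c_in
        }
      }
    }
  }
  idx
}

#' @exportS3Method
nn_fwd.nn_conv2d <- function(m, x, train = FALSE) {
  d <- dim(x)
  H <- d[2]; W <- d[3]; B <- d[4]
  h_out <- (H - m$kh) %/% m$sh + 1L
  w_out <- as.integer(ceiling(W / m$sw))
  total <- max(0L, (w_out - 1L) * m$sw + m$kw - W)
  pl <- total %/% 2L; pr <- total - pl
  if (pl > 0L || pr > 0L) {
    xp <- array(0, c(d[1], H, W + pl + pr, B))
    xp[, , (pl + 1L):(pl + W), ] <- x
  } else xp <- x
  w_pad <- dim(xp)[3]
  key <- paste0(H, ":", W, ":", w_pad)
  idx <- m$idx_cache[[key]]
  if (is.null(idx)) {
    idx <- conv2d_index(m$c_in, H, w_pad, m$kh, m$kw, m$sh, m$sw, h_out, w_out)
    m$idx_cache[[key]] <- idx
  }
  patch <- m$c_in * m$kh * m$kw
  dim(xp) <- c(m$c_in * H * w_pad, B)
  xmat <- xp[as.vector(idx), , drop = FALSE]
  dim(xmat) <- c(patch, h_out * w_out * B)             # (patch, npos*B)
  Y <- m$par$W %*% xmat + m$par$b
  m$flops <- m$flops + (2 * patch * m$c_out + m$c_out) * h_out * w_out
  list(y = array(Y, c(m$c_out, h_out, w_out, B)),
       cache = list(xmat = xmat, idx = idx, H = H, W = W, w_pad = w_pad,
                    pl = pl, B = B, npos = h_out * w_out))
}

#' @exportS3Method
nn_bwd.nn_conv2d <- function(m, cache, gy) {
  B <- cache$B
  G <- gy
  dim(G) <- c(m$c_out, cache$npos * B)
  m$gr$W <- m$gr$W + tcrossprod(G, cache$xmat)
  m$gr$b <- m$gr$b + rowSums(G)
  gxcol <- crossprod(m$par$W, G)
  dim(gxcol) <- c(length(cache$idx), B)
  rs <- rowsum(gxcol, group = as.vector(cache$idx))
  gxp <- matrix(0, m$c_in * cache$H * cache$w_pad, B)
  gxp[as.integer(rownames(rs)), ] <- rs
  gxp <- array(gxp, c(m$c_in, cache$H, cache$w_pad, B))
  gxp[, , (cache$pl + 1L):(cache$pl + cache$W), , drop = FALSE]
}

## ---- GRU --------------------------------------------------------------------
# Single-sequence recurrent layer; x: (D, T) -> h: (H, T). Gate packing order
# within the 3H rows: update (z), reset (r), candidate (h).

layer_gru <- function(d_in, d_h) {
  m <- new_module("nn_gru", d_in = d_in, d_h = d_h)
  m$par$W <- init_weights(3L * d_h, d_in, d_in)
  m$par$U <- init_weights(3L * d_h, d_h, d_h)
  m$par$b <- numeric(3L * d_h)
  m$gr$W <- matrix(0, 3L * d_h, d_in)
  m$gr$U <- matrix(0, 3L * d_h, d_h)
  m$gr$b <- numeric(3L * d_h)
  m
}

#' @exportS3Method
nn_fwd.nn_gru <- function(m, x, train = FALSE) {
  H <- m$d_h
  T <- ncol(x)
  iz <- 1:H; ir <- (H + 1):(2 * H); ih <- (2 * H + 1):(3 * H)
  WX <- m$par$W %*% x + m$par$b
  Z <- R <- Hc <- Hs <- Uh <- matrix(0, H, T)
  h <- numeric(H)
  for (t in seq_len(T)) {
    u <- m$par$U %*% h
    z <- 1 / (1 + exp(-(WX[iz, t] + u[iz])))
    r <- 1 / (1 + exp(-(WX[ir, t] + u[ir])))
    hc <- tanh(WX[ih, t] + r * u[ih])
    h <- (1 - z) * h + z * hc
    Z[, t] <- z; R[, t] <- r; Hc[, t] <- hc; Hs[, t] <- h; Uh[, t] <- u[ih]
  }
  m$flops <- m$flops + (2 * 3 * H * m$d_in + 2 * 3 * H * H + 12 * H) * T
  list(y = Hs, cache = list(x = x, Z = Z, R = R, Hc = Hc, Hs = Hs, Uh = Uh))
}

#' @exportS3Method
nn_bwd.nn_gru <- function(m, cache, gy) {
  H <- m$d_h
  T <- ncol(gy)
  iz <- 1:H; ir <- (H + 1):(2 * H); ih <- (2 * H + 1):(3 * H)
  Uz <- m$par$U[iz, , drop = FALSE]
  Ur <- m$par$U[ir, , drop = FALSE]
  Uo <- m$par$U[ih, , drop = FALSE]
  gWX <- matrix(0, 3 * H, T)
  gU <- matrix(0, 3 * H, H)
  gh_next <- numeric(H)
  for (t in rev(seq_len(T))) {
    gh <- gy[, t] + gh_next
    z <- cache$Z[, t]; r <- cache$R[, t]; hc <- cache$Hc[, t]
    h_prev <- if (t > 1L) cache$Hs[, t - 1L] else numeric(H)
    ghc <- gh * z
    gz <- gh * (hc - h_prev)
    gh_prev <- gh * (1 - z)
    a_hc <- ghc * (1 - hc^2)
    gr <- a_hc * cache$Uh[, t]
    guh <- a_hc * r
    a_z <- gz * z * (1 - z)
    a_r <- gr * r * (1 - r)
    gWX[iz, t] <- a_z; gWX[ir, t] <- a_r; gWX[ih, t] <- a_hc
    if (t > 1L) {
      gU[iz, ] <- gU[iz, ] + a_z %o% h_prev
      gU[ir, ] <- gU[ir, ] + a_r %o% h_prev
      gU[ih, ] <- gU[ih, ] + guh %o% h_prev
    }
    gh_next <- gh_prev + crossprod(Uz, a_z)[, 1] + crossprod(Ur, a_r)[, 1] +
      crossprod(Uo, guh)[, 1]
  }
  m$gr$W <- m$gr$W + tcrossprod(gWX, cache$x)
  m$gr$U <- m$gr$U + gU
  m$gr$b <- m$gr$b + rowSums(gWX)
  crossprod(m$par$W, gWX)
}

## ---- LSTM -------------------------------------------------------------------
# Gate packing order within the 4H rows: input (i), forget (f), output (o),
# candidate (g).

layer_lstm <- function(d_in, d_h) {
  m <- new_module("nn_lstm", d_in = d_in, d_h = d_h)
  m$par$W <- init_weights(4L * d_h, d_in, d_in)
  m$par$U <- init_weights(4L * d_h, d_h, d_h)
  m$par$b <- numeric(4L * d_h)
  m$gr$W <- matrix(0, 4L * d_h, d_in)
  m$gr$U <- matrix(0, 4L * d_h, d_h)
  m$gr$b <- numeric(4L * d_h)
  m
}

#' @exportS3Method
nn_fwd.nn_lstm <- function(m, x, train = FALSE) {
  H <- m$d_h
  T <- ncol(x)
  ii <- 1:H; iff <- (H + 1):(2 * H); io <- (2 * H + 1):(3 * H)
  ig <- (3 * H + 1):(4 * H)
  WX <- m$par$W %*% x + m$par$b
  I <- Ff <- O <- G <- C <- Hs <- matrix(0, H, T)
  h <- c_st <- numeric(H)
  for (t in seq_len(T)) {
    u <- m$par$U %*% h
    i <- 1 / (1 + exp(-(WX[ii, t] + u[ii])))
    f <- 1 / (1 + exp(-(WX[iff, t] + u[iff])))
    o <- 1 / (1 + exp(-(WX[io, t] + u[io])))
    g <- tanh(WX[ig, t] + u[ig])
    c_st <- f * c_st + i * g
    h <- o * tanh(c_st)
    I[, t] <- i; Ff[, t] <- f; O[, t] <- o; G[, t] <- g
    C[, t] <- c_st; Hs[, t] <- h
  }
  m$flops <- m$flops + (2 * 4 * H * m$d_in + 2 * 4 * H * H + 16 * H) * T
  list(y = Hs, cache = list(x = x, I = I, Ff = Ff, O = O, G = G, C = C,
                            Hs = Hs))
}

#' @exportS3Method
nn_bwd.nn_lstm <- function(m, cache, gy) {
  H <- m$d_h
  T <- ncol(gy)
  ii <- 1:H; iff <- (H + 1):(2 * H); io <- (2 * H + 1):(3 * H)
  ig <- (3 * H + 1):(4 * H)
  gWX <- matrix(0, 4 * H, T)
  gU <- matrix(0, 4 * H, H)
  gh_next <- gc_next <- numeric(H)
  for (t in rev(seq_len(T))) {
    gh <- gy[, t] + gh_next
    i <- cache$I[, t]; f <- cache$Ff[, t]; o <- cache$O[, t]
    g <- cache$G[, t]; c_st <- cache$C[, t]
    tc <- tanh(c_st)
    c_prev <- if (t > 1L) cache$C[, t - 1L] else numeric(H)
    h_prev <- if (t > 1L) cache$Hs[, t - 1L] else numeric(H)
    go <- gh * tc
    gc <- gh * o * (1 - tc^2) + gc_next
    gf <- gc * c_prev
    gi <- gc * g
    gg <- gc * i
    gc_next <- gc * f
    a_i <- gi * i * (1 - i); a_f <- gf * f * (1 - f)
    a_o <- go * o * (1 - o); a_g <- gg * (1 - g^2)
    gWX[ii, t] <- a_i; gWX[iff, t] <- a_f; gWX[io, t] <- a_o; gWX[ig, t] <- a_g
    if (t > 1L) {
      a_all <- c(a_i, a_f, a_o, a_g)
      gU <- gU + a_all %o% h_prev
    }
    gh_next <- crossprod(m$par$U, c(a_i, a_f, a_o, a_g))[, 1]
  }
  m$gr$W <- m$gr$W + tcrossprod(gWX, cache$x)
  m$gr$U <- m$gr$U + gU
  m$gr$b <- m$gr$b + rowSums(gWX)
  crossprod(m$par$W, gWX)
}

## ---- model container, params, Adam -----------------------------------------

# a model is an environment with class and $modules, a flat named list of
# primitive modules (shared modules appear exactly once)
new_model <- function(cls, modules, ...) {
  m <- new.env(parent = emptyenv())
  m$modules <- modules
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(cls, "nn_model")
  m
}

zero_grads <- function(model) {
  for (mod in model$modules) {
    for (nm in names(mod$gr)) mod$gr[[nm]][] <- 0
  }
  invisible(model)
}

get_params <- function(model) {
  lapply(model$modules, function(mod) mod$par)
}

set_params <- function(model, snapshot) {
  stopifnot(length(snapshot) == length(model$modules))
  for (i in seq_along(snapshot)) model$modules[[i]]$par <- snapshot[[i]]
  invisible(model)
}

reset_flops <- function(model) {
  for (mod in model$modules) mod$flops <- 0
  invisible(model)
}

total_flops <- function(model) {
  sum(vapply(model$modules, function(mod) mod$flops, numeric(1)))
}

#' Count trainable parameters of a built model
#'
#' Total number of trainable scalars (weights and biases). Weight-shared
#' modules are counted once, so e.g. the sensor-independent encoder's count
#' does not depend on the number of sensors it is applied to.
#'
#' @param model A model built by [build_encoder()] or [build_temporal()].
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "nn_model"))
  sum(vapply(model$modules, function(mod) {
    sum(vapply(mod$par, length, numeric(1)))
  }, numeric(1)))
}

adam_init <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(model$modules, function(mod) lapply(mod$par, function(p) p * 0))
  opt$v <- lapply(model$modules, function(mod) lapply(mod$par, function(p) p * 0))
  opt
}

adam_step <- function(opt, model) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(model$modules)) {
    mod <- model$modules[[i]]
    for (nm in names(mod$par)) {
      g <- mod$gr[[nm]]
      opt$m[[i]][[nm]] <- opt$beta1 * opt$m[[i]][[nm]] + (1 - opt$beta1) * g
      opt$v[[i]][[nm]] <- opt$beta2 * opt$v[[i]][[nm]] + (1 - opt$beta2) * g * g
      mhat <- opt$m[[i]][[nm]] / bc1
      vhat <- opt$v[[i]][[nm]] / bc2
      mod$par[[nm]] <- mod$par[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(opt)
}

# cross-entropy of softmax(logits) against target probabilities;
# logits, target: (K, n). Returns mean loss and gradient wrt logits.
softmax_xent <- function(logits, target) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  loss <- -sum(target * log(pmax(p, 1e-12))) / n
  list(loss = loss, grad = (p - target) / n, probs = p)
}
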