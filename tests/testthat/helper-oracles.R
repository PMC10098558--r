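# Independent oracles and small fixture builders shared across tests.

# central-difference numerical gradient of scalar f at x
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# naive sliding median with symmetrically shrinking edge windows
naive_median_filter <- function(x, width = 5L) {
  n <- length(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    r <- min(i - 1L, n - i, half)
    median(sort(x[(i - r):(i + r)]))
  }, numeric(1))
}

# exhaustive scan for the minimum-variance window mean
naive_gyro_bias <- function(x, window = 64L) {
  n <- length(x)
  vars <- vapply(seq_len(n - window + 1L), function(s) {
    var(x[s:(s + window - 1L)])
  }, numeric(1))
  s <- which.min(vars)
  mean(x[s:(s + window - 1L)])
}

# exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# choose(n+m, n) assignments of ranks to group a (no ties assumed)
enum_wilcoxon_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2      # Mann-Whitney U of a
  combos <- combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(u_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# direct piecewise-linear interpolation of (ts, ys) at point t
naive_lin_interp <- function(ts, ys, t) {
  i <- findInterval(t, ts)
  i <- pmin(pmax(i, 1L), length(ts) - 1L)
  w <- (t - ts[i]) / (ts[i + 1L] - ts[i])
  ys[i] + w * (ys[i + 1L] - ys[i])
}

# a small in-memory synthetic bundle (shared across tests, built once)
tiny_bundle <- local({
  bundle <- NULL
  function() {
    if (is.null(bundle)) {
      cfg <- synthetic_config("easy", n_recordings = 2, duration_s = 90,
                              seed = 5)
      bundle <<- make_benchmark_dataset(cfg)
    }
    bundle
  }
})

tiny_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- preprocess_dataset(tiny_bundle())
    ds
  }
})

# four very short recordings, for fold/grid bookkeeping tests
tiny4_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) {
      cfg <- synthetic_config("easy", n_recordings = 4, duration_s = 45,
                              seed = 8)
      ds <<- preprocess_dataset(make_benchmark_dataset(cfg))
    }
    ds
  }
})

# a jittered raw stream carrying a known per-channel function of time
make_test_stream <- function(sensor = "LA", n = 64L, seed = 1L,
                             fun = function(t) sin(2 * pi * 1.3 * t)) {
  set.seed(seed)
  t <- (seq_len(n) - 1L) / 52
  ts <- t + rnorm(n, 0, 0.002)
  ts[1] <- t[1]; ts[n] <- t[n]
  while (any(diff(ts) <= 0)) {
    i <- which(diff(ts) <= 0) + 1L
    ts[i] <- ts[i - 1L] + 1e-6
  }
  samples <- sapply(1:6, function(ch) fun(ts) + ch)
  raw_sensor_stream(sensor, ts, samples)
}
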