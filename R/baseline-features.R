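# Hand-crafted per-channel features and a linear multiclass baseline.
# 14 features per channel x 24 channels = 336 features per frame.

#' Names of the 14 per-channel features
#'
#' Time-domain: mean, variance, max, min, signal magnitude area (mean absolute
#' value), energy (sum of squares), interquartile range, skewness, kurtosis,
#' RMS amplitude. Frequency-domain (from the one-sided magnitude spectrum of
#' the unwindowed frame, DC excluded): frequency of the largest component,
#' magnitude-weighted mean frequency, frequency skewness, frequency kurtosis.
#'
#' @return Character vector of length 14.
#' @export
channel_feature_names <- function() {
  c("mean", "var", "max", "min", "sma", "energy", "iqr", "skew", "kurt",
    "rms", "f_peak", "f_mean", "f_skew", "f_kurt")
}

#' Extract the 14 features of one channel window
#'
#' @param channel Numeric vector (one channel of one frame, typically 120
#'   samples).
#' @param fs Sampling rate in Hz (default 52); sets the frequency axis of the
#'   spectral features.
#' @return Named numeric vector of length 14. A constant channel has zero
#'   spectral features and zero skewness/kurtosis (guarded divisions).
#' @export
extract_channel_features <- function(channel, fs = 52) {
  x <- as.numeric(channel)
  n <- length(x)
  if (n == 0L) stop("empty channel")
  mu <- mean(x)
  v <- stats::var(x)
  if (n == 1L) v <- 0
  sdev <- sqrt(v * (n - 1) / n)          # population sd for moment features
  skew <- if (sdev > 0) mean(((x - mu) / sdev)^3) else 0
  kurt <- if (sdev > 0) mean(((x - mu) / sdev)^4) else 0

  # one-sided magnitude spectrum, DC excluded
  sp <- abs(stats::fft(x))
  nb <- n %/% 2L
  mag <- sp[2:(nb + 1L)]
  freq <- (1:nb) * fs / n
  msum <- sum(mag)
  if (msum > 0) {
    f_peak <- freq[which.max(mag)]
    p <- mag / msum
    f_mean <- sum(p * freq)
    f_sd <- sqrt(sum(p * (freq - f_mean)^2))
    f_skew <- if (f_sd > 0) sum(p * ((freq - f_mean) / f_sd)^3) else 0
    f_kurt <- if (f_sd > 0) sum(p * ((freq - f_mean) / f_sd)^4) else 0
  } else {
    f_peak <- f_mean <- f_skew <- f_kurt <- 0
  }

  out <- c(mu, v, max(x), min(x), mean(abs(x)), sum(x^2),
           stats::IQR(x), skew, kurt, sqrt(mean(x^2)),
           f_peak, f_mean, f_skew, f_kurt)
  names(out) <- channel_feature_names()
  out
}

#' Extract the 336-dimensional feature vector of a frame
#'
#' Concatenates the 14 per-channel features over the 24 channels in canonical
#' order; names follow `{sensor}_{modality}_{axis}_{feature}`.
#'
#' @param frame A `(24, 120)` matrix (one frame).
#' @param fs Sampling rate in Hz.
#' @return Named numeric vector of length 336.
#' @export
extract_frame_features <- function(frame, fs = 52) {
  frame <- as.matrix(frame)
  if (nrow(frame) != 24L) stop("frame must have 24 channel rows")
  out <- numeric(24L * 14L)
  for (ch in 1:24) {
    out[((ch - 1L) * 14L + 1L):(ch * 14L)] <- extract_channel_features(
      frame[ch, ], fs)
  }
  names(out) <- as.vector(vapply(channel_names(), function(cn) {
    paste(cn, channel_feature_names(), sep = "_")
  }, character(14)))
  out
}

#' Extract features for every frame of a tensor
#'
#' @param frames Frame tensor `(n_frames, 24, 120)`.
#' @param fs Sampling rate in Hz.
#' @return `(n_frames, 336)` feature matrix with named columns.
#' @export
extract_features <- function(frames, fs = 52) {
  n <- dim(frames)[1]
  out <- matrix(0, n, 336L)
  for (i in seq_len(n)) out[i, ] <- extract_frame_features(frames[i, , ], fs)
  colnames(out) <- names(extract_frame_features(
    matrix(0, 24, dim(frames)[3]), fs))
  out
}

#' Fit the linear multiclass baseline classifier
#'
#' Standardizes features with global mean/variance normalization (the
#' transform is stored with the model) and fits a linear-kernel support vector
#' machine (one-vs-one multiclass voting). This baseline delegates to a
#' standard solver; it is a reference point, not the package's contribution.
#'
#' @param features `(n, p)` feature matrix.
#' @param labels Class labels (factor, character or integer ids), at least two
#'   distinct classes.
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `baseline_svm` with a [predict()] method.
#' @export
fit_baseline_classifier <- function(features, labels, cost = 1) {
  features <- as.matrix(features)
  y <- factor(as.character(if (is.numeric(labels))
    movement_classes()[labels] else labels))
  if (nlevels(droplevels(y)) < 2L) {
    stop("need at least two classes to fit the baseline classifier")
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  fit <- e1071::svm(xs, droplevels(y), kernel = "linear", cost = cost,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale),
            class = "baseline_svm")
}

#' Predict with the baseline classifier
#'
#' @param object A `baseline_svm` model.
#' @param newdata `(n, p)` raw (unstandardized) feature matrix.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.baseline_svm <- function(object, newdata, ...) {
  xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale,
              "/")
  stats::predict(object$fit, xs)
}
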