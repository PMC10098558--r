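# Raw packet-stream handling and the preprocessing pipeline: per-sensor
# linear interpolation onto an ideal uniform 52 Hz timebase, gyroscope bias
# estimation/removal (mean of the minimum-variance 64-sample segment),
# 5-sample median filtering, and windowing into 120-sample frames with 50%
# overlap.

#' Construct a raw sensor packet stream
#'
#' A raw stream is what one IMU delivers over the radio link: packets of four
#' consecutive samples, each sample carrying a timestamp and six channels
#' (acc x/y/z in m/s^2, gyro x/y/z in deg/s).
#'
#' @param sensor_id One of `"LA"`, `"RA"`, `"LL"`, `"RL"`.
#' @param timestamps Numeric vector of per-sample timestamps in seconds,
#'   strictly increasing; length must be a multiple of 4 (whole packets).
#' @param samples Numeric matrix with one row per timestamp and 6 columns
#'   (`acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z`).
#' @return An object of class `raw_sensor_stream`.
#' @export
raw_sensor_stream <- function(sensor_id, timestamps, samples) {
  sensor_id <- match.arg(sensor_id, sensor_ids())
  timestamps <- as.numeric(timestamps)
  samples <- as.matrix(samples)
  if (length(timestamps) == 0L) stop("empty stream")
  if (nrow(samples) != length(timestamps)) {
    stop("samples must have one row per timestamp")
  }
  if (ncol(samples) != 6L) stop("samples must have 6 channels")
  if (length(timestamps) %% 4L != 0L) {
    stop("stream length must be a whole number of 4-sample packets")
  }
  if (any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  colnames(samples) <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y",
                         "gyro_z")
  structure(list(sensor_id = sensor_id, timestamps = timestamps,
                 samples = samples), class = "raw_sensor_stream")
}

#' @export
print.raw_sensor_stream <- function(x, ...) {
  cat("<raw_sensor_stream>", x$sensor_id, ":", length(x$timestamps),
      "samples (", length(x$timestamps) %/% 4L, "packets ),",
      sprintf("%.2f s\n", diff(range(x$timestamps))))
  invisible(x)
}

#' Interpolate a packet stream onto a uniform timebase
#'
#' Piecewise-linear interpolation of each of the six channels from the
#' recorded (jittered) timestamps onto an ideal uniform grid anchored at the
#' first recorded timestamp. No extrapolation beyond the last timestamp.
#'
#' @param stream A [raw_sensor_stream()].
#' @param fs Target sampling rate in Hz (default 52).
#' @param grid Optional explicit grid of output times (overrides `fs` grid);
#'   must lie within the stream's time range.
#' @return A list with `signal` (6 x n matrix, channel-major) and `times`
#'   (the uniform grid).
#' @export
interpolate_to_uniform <- function(stream, fs = 52, grid = NULL) {
  stopifnot(inherits(stream, "raw_sensor_stream"))
  ts <- stream$timestamps
  if (length(ts) < 8L) stop("need at least 2 packets to interpolate")
  if (is.null(grid)) {
    grid <- seq(ts[1], ts[length(ts)], by = 1 / fs)
  } else {
    if (min(grid) < ts[1] || max(grid) > ts[length(ts)]) {
      stop("grid extends beyond the recorded time range")
    }
  }
  sig <- matrix(0, 6L, length(grid))
  for (ch in 1:6) {
    sig[ch, ] <- stats::approx(ts, stream$samples[, ch], xout = grid,
                               method = "linear", rule = 1)$y
  }
  rownames(sig) <- colnames(stream$samples)
  list(signal = sig, times = grid)
}

#' Estimate a gyroscope channel's constant bias
#'
#' The bias is the mean of the contiguous `window`-sample segment with the
#' smallest variance in the recording, i.e. the quietest stretch, where the
#' gyroscope should read zero angular velocity.
#'
#' @param channel Numeric signal vector (length >= `window`).
#' @param window Segment length in samples (default 64).
#' @return The estimated bias (scalar); subtract it from the channel.
#' @export
estimate_gyro_bias <- function(channel, window = 64L) {
  n <- length(channel)
  window <- as.integer(window)
  if (n < window) stop("channel shorter than the bias window (", window, ")")
  # O(n) sliding sums: variance of each window up to a constant factor
  cs <- cumsum(c(0, channel))
  cs2 <- cumsum(c(0, channel^2))
  s1 <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
  s2 <- cs2[(window + 1L):(n + 1L)] - cs2[1:(n - window + 1L)]
  ssd <- s2 - s1^2 / window            # window sum of squared deviations
  i <- which.min(ssd)
  s1[i] / window
}

#' Median filter one channel
#'
#' Running median of odd width (default 5). Edges use symmetrically shrinking
#' windows (width 1 and 3 at the boundaries), so no data beyond the recording
#' is invented.
#'
#' @param channel Numeric signal vector.
#' @param width Odd window width (default 5).
#' @return Filtered vector of the same length.
#' @export
median_filter_channel <- function(channel, width = 5L) {
  width <- as.integer(width)
  if (width %% 2L == 0L) stop("median filter width must be odd")
  n <- length(channel)
  half <- width %/% 2L
  shrunk <- function(i) {
    r <- min(i - 1L, n - i, half)
    stats::median(channel[(i - r):(i + r)])
  }
  if (n <= width) return(vapply(seq_len(n), shrunk, numeric(1)))
  out <- as.numeric(stats::runmed(channel, width, endrule = "keep"))
  edge <- c(seq_len(half), (n - half + 1L):n)
  out[edge] <- vapply(edge, shrunk, numeric(1))
  out
}

#' Preprocess four raw streams into a uniform 24-channel recording
#'
#' The full pipeline: all four sensors are linearly interpolated onto one
#' shared uniform grid (spanning the intersection of their time ranges, at
#' `fs` Hz), each gyroscope channel has its estimated constant bias
#' subtracted, and every channel is median filtered. Rows are assembled in the
#' canonical sensor-major order ([channel_names()]).
#'
#' @param streams List of four [raw_sensor_stream()] objects covering all of
#'   LA, RA, LL, RL.
#' @param fs Sampling rate of the ideal timebase (default 52 Hz).
#' @param bias_window Gyro-bias segment length (default 64 samples).
#' @param median_width Median filter width (default 5).
#' @return An object of class `uniform_recording`: list with `signal`
#'   (24 x n matrix), `fs`, and `t0` (grid start time).
#' @export
preprocess_recording <- function(streams, fs = 52, bias_window = 64L,
                                 median_width = 5L) {
  if (!is.list(streams) || length(streams) != 4L) {
    stop("need all four sensor streams (missing sensors are a test-time ",
         "robustness condition, simulated downstream)")
  }
  ids <- vapply(streams, function(s) s$sensor_id, character(1))
  if (!setequal(ids, sensor_ids())) {
    stop("streams must cover exactly the sensors ",
         paste(sensor_ids(), collapse = ", "))
  }
  streams <- streams[match(sensor_ids(), ids)]
  t_start <- max(vapply(streams, function(s) s$timestamps[1], numeric(1)))
  t_end <- min(vapply(streams, function(s) max(s$timestamps), numeric(1)))
  if (t_end <= t_start) stop("sensor time ranges do not overlap")
  grid <- seq(t_start, t_end, by = 1 / fs)
  sig <- matrix(0, 24L, length(grid))
  for (s in 1:4) {
    sig[sensor_rows(s), ] <- interpolate_to_uniform(streams[[s]],
                                                    grid = grid)$signal
  }
  for (ch in gyro_rows()) {
    sig[ch, ] <- sig[ch, ] - estimate_gyro_bias(sig[ch, ], bias_window)
  }
  for (ch in 1:24) {
    sig[ch, ] <- median_filter_channel(sig[ch, ], median_width)
  }
  rownames(sig) <- channel_names()
  structure(list(signal = sig, fs = fs, t0 = t_start),
            class = "uniform_recording")
}

#' @export
print.uniform_recording <- function(x, ...) {
  cat("<uniform_recording> 24 x", ncol(x$signal), "samples @", x$fs, "Hz (",
      sprintf("%.1f s )\n", ncol(x$signal) / x$fs))
  invisible(x)
}

#' Window a uniform recording into overlapping frames
#'
#' Rectangular windows of `frame_len` samples every `hop` samples (default:
#' 120-sample frames, 2.3 s at 52 Hz, with 50% overlap). Frame `i` (1-based)
#' covers samples `[hop*(i-1) + 1, hop*(i-1) + frame_len]`; the trailing
#' remainder is discarded.
#'
#' @param rec A `uniform_recording` or a bare 24 x n signal matrix.
#' @param frame_len Frame length in samples (default 120).
#' @param hop Hop size in samples (default 60).
#' @return Frame tensor, an array of shape `(n_frames, 24, frame_len)`.
#' @export
window_frames <- function(rec, frame_len = 120L, hop = 60L) {
  sig <- if (inherits(rec, "uniform_recording")) rec$signal else as.matrix(rec)
  n <- ncol(sig)
  frame_len <- as.integer(frame_len)
  hop <- as.integer(hop)
  if (n < frame_len) {
    warning("recording shorter than one frame; returning zero frames")
    return(array(0, c(0L, nrow(sig), frame_len)))
  }
  n_frames <- (n - frame_len) %/% hop + 1L
  frames <- array(0, c(n_frames, nrow(sig), frame_len))
  for (i in seq_len(n_frames)) {
    frames[i, , ] <- sig[, (hop * (i - 1L) + 1L):(hop * (i - 1L) + frame_len)]
  }
  frames
}

#' Convert a count of frame hops to seconds
#'
#' One frame hop is 60 samples at 52 Hz, so `n` hops span `n * 60 / 52`
#' seconds; 60 hops span 69.2 s.
#'
#' @param n_frames Non-negative frame count.
#' @param hop Hop size in samples (default 60).
#' @param fs Sampling rate in Hz (default 52).
#' @return Seconds (numeric).
#' @export
frames_to_seconds <- function(n_frames, hop = 60L, fs = 52) {
  if (any(n_frames < 0)) stop("frame count must be non-negative")
  n_frames * hop / fs
}

## ---- file formats -------------------------------------------------------------

#' Write / read a raw sensor stream as CSV
#'
#' One CSV per sensor with columns
#' `packet_id, timestamp_s, acc_x, acc_y, acc_z, gyro_x, gyro_y, gyro_z`;
#' the 4-row packet grouping is carried by `packet_id`.
#'
#' @param stream A [raw_sensor_stream()].
#' @param path Output file path.
#' @return `write_stream_csv`: the path, invisibly. `read_stream_csv`: a
#'   [raw_sensor_stream()].
#' @export
write_stream_csv <- function(stream, path) {
  stopifnot(inherits(stream, "raw_sensor_stream"))
  df <- data.frame(
    packet_id = rep(seq_len(length(stream$timestamps) %/% 4L), each = 4L),
    timestamp_s = stream$timestamps,
    stream$samples
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @param sensor_id Sensor id of the stream being read.
#' @export
read_stream_csv <- function(path, sensor_id) {
  df <- utils::read.csv(path)
  need <- c("packet_id", "timestamp_s", "acc_x", "acc_y", "acc_z",
            "gyro_x", "gyro_y", "gyro_z")
  if (!all(need %in% names(df))) {
    stop("stream CSV must have columns: ", paste(need, collapse = ", "))
  }
  raw_sensor_stream(sensor_id, df$timestamp_s,
                    as.matrix(df[, need[3:8]]))
}

#' Write / read a frame label track as CSV
#'
#' Hard labels are stored as `frame_index, class`; soft labels as
#' `frame_index` plus one probability column per movement class.
#'
#' @param labels Factor/character vector of hard labels, or a
#'   `(n_frames, 7)` matrix of soft labels (rows sum to 1).
#' @param path File path.
#' @return `write_labels_csv`: the path, invisibly. `read_labels_csv`: a
#'   factor (hard) or probability matrix (soft).
#' @export
write_labels_csv <- function(labels, path) {
  if (is.matrix(labels)) {
    stopifnot(ncol(labels) == 7L)
    if (max(abs(rowSums(labels) - 1)) > 1e-6) {
      stop("soft labels must sum to 1 per frame")
    }
    df <- data.frame(frame_index = seq_len(nrow(labels)), labels)
    names(df)[-1] <- movement_classes()
  } else {
    df <- data.frame(frame_index = seq_along(labels),
                     class = as.character(labels))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("class" %in% names(df)) {
    return(factor(df$class, levels = movement_classes()))
  }
  if (all(movement_classes() %in% names(df))) {
    return(as.matrix(df[, movement_classes()]))
  }
  stop("labels CSV must have a 'class' column or 7 class probability columns")
}

#' Save / load a preprocessed frame tensor container
#'
#' Runtime container (RDS) bundling the `(n_frames, 24, 120)` tensor with the
#' canonical channel-order metadata and sampling parameters.
#'
#' @param frames Frame tensor from [window_frames()].
#' @param path File path.
#' @param fs,hop Sampling metadata stored alongside.
#' @return `write_frames_container`: path, invisibly;
#'   `read_frames_container`: list with `frames`, `channels`, `fs`, `hop`.
#' @export
write_frames_container <- function(frames, path, fs = 52, hop = 60L) {
  saveRDS(list(frames = frames, channels = channel_names(), fs = fs,
               hop = hop), path)
  invisible(path)
}

#' @rdname write_frames_container
#' @export
read_frames_container <- function(path) {
  readRDS(path)
}
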