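# Training-time data augmentation operators: elementwise (inverted) dropout at
# the input or bottleneck, whole-sensor dropout, per-sensor Euler rotations,
# and sinusoidal time warping. All operators are identity in evaluation mode;
# the training loop applies them in the fixed order
# rotation -> time warp -> input dropout -> sensor dropout, with bottleneck
# dropout applied between the encoder and the temporal module.

#' Augmentation configuration
#'
#' @param input_dropout_p Probability of zeroing each input scalar (0
#'   disables; the study setting is 0.3).
#' @param bottleneck_dropout_p Probability of zeroing each bottleneck feature
#'   (study setting 0.3).
#' @param sensor_dropout_p Probability that one (uniformly chosen) sensor is
#'   zeroed for a whole minibatch (study setting 0.3).
#' @param rotation_max_deg Bound of the uniform yaw/pitch/roll angles in
#'   degrees (study setting 10); 0 disables rotation.
#' @param timewarp Logical: enable per-frame sinusoidal time warping with
#'   amplitude, frequency and phase each drawn uniformly from `[0, 1]`.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(input_dropout_p = 0,
                                bottleneck_dropout_p = 0,
                                sensor_dropout_p = 0,
                                rotation_max_deg = 0,
                                timewarp = FALSE) {
  stopifnot(input_dropout_p >= 0, input_dropout_p <= 1,
            bottleneck_dropout_p >= 0, bottleneck_dropout_p <= 1,
            sensor_dropout_p >= 0, sensor_dropout_p <= 1,
            rotation_max_deg >= 0)
  structure(list(input_dropout_p = input_dropout_p,
                 bottleneck_dropout_p = bottleneck_dropout_p,
                 sensor_dropout_p = sensor_dropout_p,
                 rotation_max_deg = rotation_max_deg,
                 timewarp = isTRUE(timewarp)),
            class = "augmentation_config")
}

# named preset matching the robustness-experiment key:
# dr1 = input dropout, dr2 = bottleneck dropout, rot = rotation,
# tw = time warping, drs = sensor dropout
#' Named augmentation presets
#'
#' Builds an [augmentation_config()] from short keys: `"none"`, `"dr1"`
#' (input dropout 0.3), `"dr2"` (bottleneck dropout 0.3), `"rot"` (rotation
#' within ±10 degrees), `"tw"` (time warping), `"drs"` (sensor dropout 0.3).
#' Several keys can be combined, e.g. `c("dr1", "drs")`.
#'
#' @param keys Character vector of preset keys.
#' @return An [augmentation_config()].
#' @export
augmentation_preset <- function(keys = "none") {
  keys <- match.arg(keys, c("none", "dr1", "dr2", "rot", "tw", "drs"),
                    several.ok = TRUE)
  augmentation_config(
    input_dropout_p = if ("dr1" %in% keys) 0.3 else 0,
    bottleneck_dropout_p = if ("dr2" %in% keys) 0.3 else 0,
    sensor_dropout_p = if ("drs" %in% keys) 0.3 else 0,
    rotation_max_deg = if ("rot" %in% keys) 10 else 0,
    timewarp = "tw" %in% keys
  )
}

#' Euler rotation matrix R = Rz(alpha) Ry(beta) Rx(gamma)
#'
#' Product of the elementary yaw (z), pitch (y) and roll (x) rotations, in
#' that order.
#'
#' @param alpha,beta,gamma Yaw, pitch, roll angles in radians.
#' @return A 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @export
euler_rotation_matrix <- function(alpha, beta, gamma) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(gamma))
  rz <- matrix(c(cos(alpha), sin(alpha), 0,
                 -sin(alpha), cos(alpha), 0,
                 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(beta), 0, -sin(beta),
                 0, 1, 0,
                 sin(beta), 0, cos(beta)), 3, 3)
  rx <- matrix(c(1, 0, 0,
                 0, cos(gamma), sin(gamma),
                 0, -sin(gamma), cos(gamma)), 3, 3)
  rz %*% ry %*% rx
}

#' Draw per-sensor rotation angles
#'
#' Yaw, pitch and roll sampled independently and uniformly within
#' `±max_deg` degrees for each of the four sensors.
#'
#' @param max_deg Angle bound in degrees.
#' @return List of four numeric 3-vectors (radians), named by sensor.
#' @export
sample_rotation_angles <- function(max_deg = 10) {
  bound <- max_deg * pi / 180
  out <- lapply(1:4, function(s) stats::runif(3, -bound, bound))
  names(out) <- sensor_ids()
  out
}

#' Rotate each sensor's accelerometer and gyroscope triads
#'
#' For each sensor the same rotation matrix multiplies its accelerometer triad
#' and its gyroscope triad at every sample, emulating variation in how the
#' sensor sits on the limb.
#'
#' @param frames Frame tensor `(n_frames, 24, 120)` or a single `(24, T)`
#'   frame.
#' @param angles List of four angle 3-vectors (radians), as from
#'   [sample_rotation_angles()].
#' @return Rotated frames, same shape.
#' @export
apply_sensor_rotation <- function(frames, angles) {
  stopifnot(is.list(angles), length(angles) == 4L)
  single <- length(dim(frames)) == 2L
  if (single) frames <- array(frames, c(1L, dim(frames)))
  d <- dim(frames)
  if (d[2] != 24L) stop("frames must have 24 channels")
  for (s in 1:4) {
    R <- euler_rotation_matrix(angles[[s]][1], angles[[s]][2], angles[[s]][3])
    rows <- sensor_rows(s)
    for (triad in list(rows[1:3], rows[4:6])) {
      x <- frames[, triad, , drop = FALSE]              # (n, 3, T)
      xm <- matrix(aperm(x, c(2, 1, 3)), nrow = 3L)     # (3, n*T)
      xr <- R %*% xm
      frames[, triad, ] <- aperm(array(xr, c(3L, d[1], d[3])), c(2, 1, 3))
    }
  }
  if (single) frames <- array(frames, d[2:3])
  frames
}

#' Sinusoidally time-warp one frame
#'
#' Builds a new timestamp-differential vector
#' `dt_new(t) = 2 + A sin(2 pi omega t + 2 pi phi)` over the frame's old
#' timebase, integrates it to a warped timebase, rescales the result to span
#' exactly the original frame duration (preserving the frame length), and
#' linearly re-interpolates every channel at the warped sample times. `A = 0`
#' is the identity; constant channels are unchanged by any warp.
#'
#' @param frame `(24, 120)` matrix (or any channels x T matrix).
#' @param A Amplitude in `[0, 1]` (values above 1 would break monotonicity).
#' @param omega Frequency, uniform `[0, 1]` in the study setting.
#' @param phi Phase, uniform `[0, 1]`.
#' @param fs Sampling rate in Hz.
#' @return Warped frame, same shape.
#' @export
time_warp_frame <- function(frame, A, omega, phi, fs = 52) {
  if (A < 0 || A > 1) stop("time-warp amplitude A must be in [0, 1]")
  frame <- as.matrix(frame)
  T <- ncol(frame)
  t_old <- (seq_len(T) - 1L) / fs
  dt_new <- 2 + A * sin(2 * pi * omega * t_old + 2 * pi * phi)
  t_new <- c(0, cumsum(dt_new[-T]))
  # rescale so the warped timebase spans exactly the original duration
  t_new <- t_new / t_new[T] * t_old[T]
  out <- frame
  for (ch in seq_len(nrow(frame))) {
    out[ch, ] <- stats::approx(t_old, frame[ch, ], xout = t_new,
                               method = "linear", rule = 2)$y
  }
  out
}

# warp every frame of a tensor with fresh (A, omega, phi) per frame
time_warp_frames <- function(frames) {
  n <- dim(frames)[1]
  for (i in seq_len(n)) {
    p <- stats::runif(3)
    frames[i, , ] <- time_warp_frame(frames[i, , ], p[1], p[2], p[3])
  }
  frames
}

#' Elementwise (inverted) dropout
#'
#' Each scalar is independently zeroed with probability `p`; survivors are
#' scaled by `1 / (1 - p)` so the expected value is preserved and inference
#' needs no compensation. `train = FALSE` is the identity.
#'
#' @param x Numeric array or matrix (input frames or bottleneck features).
#' @param p Dropout probability in `[0, 1]`.
#' @param train Apply the mask (`TRUE`) or pass through (`FALSE`).
#' @return Masked (and rescaled) array of the same shape.
#' @export
input_dropout <- function(x, p, train = TRUE) {
  stopifnot(p >= 0, p <= 1)
  if (!train || p == 0) return(x)
  if (p == 1) return(x * 0)
  mask <- stats::runif(length(x)) >= p
  x * mask / (1 - p)
}

#' @rdname input_dropout
#' @export
bottleneck_dropout <- input_dropout

#' Sensor dropout augmentation for a minibatch
#'
#' With probability `p`, one sensor chosen uniformly at random has its six
#' channels zeroed for every frame of the minibatch; otherwise the input
#' passes through unchanged.
#'
#' @param frames Frame tensor `(n_frames, 24, 120)`.
#' @param p Trigger probability in `[0, 1]`.
#' @param train Apply (`TRUE`) or pass through (`FALSE`).
#' @return Frames with possibly one sensor zeroed.
#' @export
sensor_dropout_augment <- function(frames, p, train = TRUE) {
  stopifnot(p >= 0, p <= 1)
  if (!train || p == 0) return(frames)
  if (stats::runif(1) < p) {
    s <- sample.int(4L, 1L)
    frames[, sensor_rows(s), ] <- 0
  }
  frames
}

# apply the configured train-time operators to a minibatch of frames
# (bottleneck dropout is applied separately, between encoder and temporal)
augment_minibatch <- function(frames, aug) {
  if (aug$rotation_max_deg > 0) {
    frames <- apply_sensor_rotation(frames,
                                    sample_rotation_angles(aug$rotation_max_deg))
  }
  if (aug$timewarp) frames <- time_warp_frames(frames)
  if (aug$input_dropout_p > 0) {
    frames <- input_dropout(frames, aug$input_dropout_p)
  }
  if (aug$sensor_dropout_p > 0) {
    frames <- sensor_dropout_augment(frames, aug$sensor_dropout_p)
  }
  frames
}
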