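#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical movement class labels
#'
#' The seven movement categories, in canonical order: still, proto movement,
#' turn left/right, pivot left/right, commando crawl.
#'
#' @return Character vector of length 7.
#' @export
movement_classes <- function() {
  c("Still", "Proto", "TurnL", "TurnR", "PivotL", "PivotR", "CrawlCommando")
}

#' Canonical sensor identifiers
#'
#' Four limb-mounted IMUs: left arm, right arm, left leg, right leg.
#'
#' @return Character vector of length 4.
#' @export
sensor_ids <- function() c("LA", "RA", "LL", "RL")

#' Canonical 24-channel names
#'
#' Sensor-major ordering (LA, RA, LL, RL), accelerometer before gyroscope,
#' x/y/z within each modality. This is the fixed row order of a preprocessed
#' recording matrix and of every frame tensor.
#'
#' @return Character vector of length 24, e.g. `"LA_acc_x"`.
#' @export
channel_names <- function() {
  mods <- c("acc", "gyr")
  axes <- c("x", "y", "z")
  as.vector(vapply(sensor_ids(), function(s) {
    as.vector(vapply(mods, function(m) paste(s, m, axes, sep = "_"),
                     character(3)))
  }, character(6)))
}

# row indices of a sensor's channels in the 24-row canonical layout
sensor_rows <- function(sensor) {
  s <- if (is.character(sensor)) match(sensor, sensor_ids()) else as.integer(sensor)
  stopifnot(!is.na(s), s >= 1L, s <= 4L)
  (s - 1L) * 6L + 1:6
}

acc_rows <- function() as.vector(vapply(0:3, function(s) s * 6L + 1:3, integer(3)))
gyro_rows <- function() as.vector(vapply(0:3, function(s) s * 6L + 4:6, integer(3)))

# numerically stable column-wise softmax of a (K, n) matrix
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

# one-hot encode integer class ids (1..K) into a (K, n) matrix
one_hot <- function(y, n_classes) {
  y <- as.integer(y)
  stopifnot(all(y >= 1L), all(y <= n_classes))
  m <- matrix(0, n_classes, length(y))
  m[cbind(y, seq_along(y))] <- 1
  m
}

# small content hash (FNV-1a over serialized bytes); used for config hashes in
# experiment reports so a grid row can be re-run exactly
fnv1a_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (v in b) {
    h <- bitwXor(as.integer(h %% 2^31), v)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# coerce labels (factor / character / integer) to integer ids in 1..7
as_class_ids <- function(labels, classes = movement_classes()) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ids <- match(labels, classes)
    if (anyNA(ids)) stop("unknown class label(s): ",
                         paste(unique(labels[is.na(ids)]), collapse = ", "))
    return(ids)
  }
  as.integer(labels)
}
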