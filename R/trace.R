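#' Construct a triaxial acceleration trace
#'
#' An acceleration trace is a tibble with one row per sample and columns
#' `time` (seconds since the start of the recording), `ax`, `ay`, `az`
#' (acceleration in units of g along the three sensor axes).  The sampling
#' rate is carried as the `fs` attribute so that downstream stages never have
#' to re-infer it.  Lower-back recordings of the kind this package targets
#' are nominally sampled at 100 Hz over a +/- 8 g range, but any positive
#' rate is accepted; frame-count parameters stated at 100 Hz are rescaled
#' internally.
#'
#' @param ax,ay,az Numeric vectors of equal length: per-sample acceleration
#'   in g along each axis.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Optional start clock time (`POSIXct`), carried as an attribute.
#' @return A tibble of class `accel_trace` with columns `time`, `ax`, `ay`,
#'   `az` and attributes `fs` and (optionally) `t0`.
#' @examples
#' tr <- accel_trace(ax = rnorm(500, 0, 0.01), ay = rnorm(500, 0, 0.01),
#'                   az = 1 + rnorm(500, 0, 0.01), fs = 100)
#' trace_fs(tr)
#' @export
accel_trace <- function(ax, ay, az, fs, t0 = NULL) {
  n <- length(ax)
  if (n < 1L || length(ay) != n || length(az) != n) {
    abort("ax, ay, az must be non-empty vectors of equal length",
          class = "gaitbouts_error_trace")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("fs must be a single positive number (Hz)",
          class = "gaitbouts_error_parameter")
  }
  bad <- which(!is.finite(ax) | !is.finite(ay) | !is.finite(az))
  if (length(bad) > 0L) {
    abort(paste0("non-finite acceleration sample(s), first at row ", bad[1]),
          class = "gaitbouts_error_trace")
  }
  out <- tibble(
    time = (seq_len(n) - 1L) / fs,
    ax = as.numeric(ax), ay = as.numeric(ay), az = as.numeric(az)
  )
  attr(out, "fs") <- as.numeric(fs)
  if (!is.null(t0)) attr(out, "t0") <- t0
  class(out) <- c("accel_trace", class(out))
  out
}

#' Coerce a data frame to an acceleration trace
#'
#' @param x A data frame with columns `ax`, `ay`, `az` and optionally `time`.
#' @param fs Sampling rate in Hz.  If `NULL`, it is inferred from the `time`
#'   column (median spacing), which must then be present and regular.
#' @return An [accel_trace()].
#' @export
as_accel_trace <- function(x, fs = NULL) {
  if (inherits(x, "accel_trace") && is.null(fs)) return(x)
  x <- as.data.frame(x)
  need <- c("ax", "ay", "az")
  if (!all(need %in% names(x))) {
    abort("data frame must have columns ax, ay, az",
          class = "gaitbouts_error_trace")
  }
  if (is.null(fs)) {
    if (!"time" %in% names(x)) {
      abort("fs not given and no time column to infer it from",
            class = "gaitbouts_error_parameter")
    }
    dt <- diff(x$time)
    if (length(dt) < 1L || any(dt <= 0)) {
      abort("time column is not strictly increasing",
            class = "gaitbouts_error_trace")
    }
    if (max(dt) - min(dt) > 0.01 * median(dt)) {
      abort("time column is not regularly sampled; pass fs explicitly",
            class = "gaitbouts_error_trace")
    }
    fs <- 1 / median(dt)
  }
  accel_trace(x$ax, x$ay, x$az, fs = fs)
}

#' Sampling rate and length helpers
#'
#' @param x An `accel_trace`, `activity_signal` or `label_series`.
#' @return `trace_fs()` returns the sampling rate in Hz; `n_frames()` the
#'   number of samples.
#' @export
trace_fs <- function(x) {
  fs <- attr(x, "fs")
  if (is.null(fs)) abort("object has no sampling-rate attribute",
                         class = "gaitbouts_error_parameter")
  fs
}

#' @rdname trace_fs
#' @export
n_frames <- function(x) nrow(x)

#' Rotate a trace by a fixed sensor orientation
#'
#' Applies one 3x3 rotation matrix to every sample, emulating an arbitrary
#' fixed mounting orientation of the sensor.  The detection pipeline operates
#' on the 3D norm and is invariant to this operation.
#'
#' @param trace An [accel_trace()].
#' @param rotation A 3x3 orthonormal matrix.
#' @return The rotated `accel_trace`.
#' @export
rotate_trace <- function(trace, rotation) {
  check_rotation(rotation)
  m <- rotation %*% rbind(trace$ax, trace$ay, trace$az)
  accel_trace(m[1, ], m[2, ], m[3, ], fs = trace_fs(trace),
              t0 = attr(trace, "t0"))
}

check_rotation <- function(rotation) {
  if (!is.matrix(rotation) || !all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort("rotation must be a 3x3 orthonormal matrix",
          class = "gaitbouts_error_parameter")
  }
  invisible(rotation)
}

#' Rotation matrices from Euler angles, and random rotations
#'
#' `euler_rotation()` composes intrinsic rotations about the x, y and z axes;
#' `random_rotation()` draws a rotation uniformly (QR of a Gaussian matrix,
#' sign-fixed), using the current RNG state.
#'
#' @param roll,pitch,yaw Angles in radians about the x, y and z axes.
#' @return A 3x3 rotation matrix with determinant +1.
#' @export
euler_rotation <- function(roll = 0, pitch = 0, yaw = 0) {
  rx <- matrix(c(1, 0, 0, 0, cos(roll), sin(roll), 0, -sin(roll), cos(roll)), 3)
  ry <- matrix(c(cos(pitch), 0, -sin(pitch), 0, 1, 0, sin(pitch), 0, cos(pitch)), 3)
  rz <- matrix(c(cos(yaw), sin(yaw), 0, -sin(yaw), cos(yaw), 0, 0, 0, 1), 3)
  rz %*% ry %*% rx
}

#' @rdname euler_rotation
#' @export
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_d)
  q <- q %*% diag(sign(diag(qr.R(qr_d))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Construct a per-sample activity signal
#'
#' A single nonnegative series sharing a trace's time base: either the
#' detrended 3D magnitude (units g) or a smoothed, dimensionless companion
#' such as the activity likelihood.
#'
#' @param values Numeric vector of per-sample values.
#' @param fs Sampling rate in Hz.
#' @return A tibble of class `activity_signal` with columns `time`, `value`.
#' @export
activity_signal <- function(values, fs) {
  if (any(!is.finite(values))) {
    abort("activity signal contains non-finite values",
          class = "gaitbouts_error_signal")
  }
  out <- tibble(time = (seq_along(values) - 1L) / fs, value = as.numeric(values))
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("activity_signal", class(out))
  out
}

#' Construct a per-sample binary label series
#'
#' @param labels Integer/numeric vector of 0s and 1s (1 = walking).
#' @param fs Sampling rate in Hz.
#' @return A tibble of class `label_series` with columns `time`, `label`.
#' @export
label_series <- function(labels, fs) {
  lv <- as.integer(labels)
  if (any(is.na(lv)) || !all(lv %in% c(0L, 1L))) {
    abort("labels must contain only 0 and 1",
          class = "gaitbouts_error_labels")
  }
  out <- tibble(time = (seq_along(lv) - 1L) / fs, label = lv)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("label_series", class(out))
  out
}
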