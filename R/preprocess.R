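# Zero-phase Butterworth machinery -------------------------------------------

# Steady-state initial conditions for the direct-form-II-transposed
# recursion: the state that makes the step response exact from sample one.
lfilter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  comp <- rbind(-a[-1], cbind(diag(nf - 2L), 0))  # companion matrix of a
  rhs <- b[-1] - a[-1] * b[1]
  solve(diag(nf - 1L) - t(comp), rhs)
}

# Forward-backward filtering with odd-reflection padding of length
# 3 x (coefficient count), so no phase delay and tame edges.
zero_phase_filter <- function(x, b, a) {
  n <- length(x)
  padlen <- 3L * max(length(b), length(a))
  if (n <= padlen) {
    abort("trace too short for stable zero-phase filtering",
          class = "gaitbouts_error_trace_short")
  }
  ext <- c(2 * x[1] - x[(padlen + 1L):2L],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(iir_filter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + n)]
}

butter_lowpass <- function(cutoff_hz, fs, order) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    abort("cutoff_hz must lie strictly between 0 and the Nyquist frequency",
          class = "gaitbouts_error_parameter")
  }
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  list(b = flt$b, a = flt$a)
}

#' Detrend a trace by subtracting its zero-phase low-pass estimate
#'
#' Each axis is filtered with a 4th-order zero-lag (forward-backward)
#' Butterworth low pass at 0.25 Hz and the filtered series is subtracted
#' from the raw one.  This centres the accelerations around 0 g, removing
#' gravity and slow postural offsets while preserving the frequency content
#' produced by movement (gait fundamentals and harmonics sit well above the
#' cutoff, where the complementary gain is within 1% of unity).
#'
#' @param trace An [accel_trace()].
#' @param cutoff_hz Low-pass cutoff in Hz; must lie in (0, fs/2).
#' @param order Butterworth order.
#' @return An `accel_trace` of identical length with near-DC content removed
#'   from each axis.
#' @examples
#' tr <- accel_trace(rep(0.1, 2000), rep(0.3, 2000), rep(0.95, 2000), fs = 100)
#' max(abs(detrend(tr)$az))  # a constant trace detrends to ~0
#' @export
detrend <- function(trace, cutoff_hz = 0.25, order = 4L) {
  fs <- trace_fs(trace)
  flt <- butter_lowpass(cutoff_hz, fs, order)
  padlen <- 3L * max(length(flt$b), length(flt$a))
  if (nrow(trace) <= 3L * padlen) {
    abort("trace too short for stable zero-phase filtering",
          class = "gaitbouts_error_trace_short")
  }
  accel_trace(
    trace$ax - zero_phase_filter(trace$ax, flt$b, flt$a),
    trace$ay - zero_phase_filter(trace$ay, flt$b, flt$a),
    trace$az - zero_phase_filter(trace$az, flt$b, flt$a),
    fs = fs, t0 = attr(trace, "t0")
  )
}

#' 3D magnitude (Euclidean norm) of a trace
#'
#' Collapses the three axes into a single overall-acceleration signal,
#' `sqrt(ax^2 + ay^2 + az^2)` per sample.  The norm is invariant to any fixed
#' sensor orientation, which is what makes the whole pipeline
#' orientation-independent.
#'
#' @param trace An [accel_trace()] (normally the detrended trace).
#' @return An [activity_signal()] in units of g, nonnegative everywhere.
#' @export
magnitude3d <- function(trace) {
  activity_signal(sqrt(trace$ax^2 + trace$ay^2 + trace$az^2),
                  fs = trace_fs(trace))
}

#' Gaussian smoothing kernel
#'
#' A symmetric Gaussian-weighted moving-average kernel: previous and upcoming
#' samples get equal weight, with closer samples weighted higher.  Weights
#' sum to one.
#'
#' @param window_samples Odd positive integer: kernel support in samples.
#' @param sigma_samples Positive real: Gaussian standard deviation in samples.
#' @return An object of class `gaussian_kernel`: a list with `window_samples`,
#'   `sigma_samples` and normalized `weights`.
#' @export
gaussian_kernel <- function(window_samples, sigma_samples = window_samples / 20) {
  if (window_samples < 1L || window_samples %% 2L != 1L) {
    abort("window_samples must be an odd positive integer",
          class = "gaitbouts_error_parameter")
  }
  if (!is.numeric(sigma_samples) || sigma_samples <= 0) {
    abort("sigma_samples must be positive", class = "gaitbouts_error_parameter")
  }
  half <- (window_samples - 1L) / 2L
  w <- exp(-0.5 * ((-half):half / sigma_samples)^2)
  structure(
    list(window_samples = as.integer(window_samples),
         sigma_samples = as.numeric(sigma_samples),
         weights = w / sum(w)),
    class = "gaussian_kernel"
  )
}

# Kernel parameters are stated at the nominal 100 Hz (2 s window, sigma =
# window/20 = 0.1 s) and rescaled for other rates, rounded to an odd count.
# Sigma must bridge sub-second dips through the activity threshold yet leave
# the > 0.4 g signature of 1-2 s sit-stand pulses visible to the heuristic.
default_kernel <- function(fs, window_seconds = 2, sigma_divisor = 20) {
  w <- round(window_seconds * fs)
  if (w %% 2L == 0L) w <- w + 1L
  gaussian_kernel(as.integer(w), w / sigma_divisor)
}

#' Gaussian-weighted moving average
#'
#' Smooths a per-sample signal with a [gaussian_kernel()].  At the edges the
#' kernel is truncated and renormalized so the output keeps the input length
#' and stationary edges are not dragged toward zero.  Applied to the binary
#' above-threshold series this yields the activity likelihood in \[0, 1\];
#' applied to the detrended magnitude it yields the smoothed magnitude used
#' by the transition-rejection heuristic.
#'
#' @param signal An [activity_signal()].
#' @param kernel A [gaussian_kernel()]; defaults to a 2 s window at the
#'   signal's sampling rate.
#' @return An `activity_signal` of the same length, bounded by the input's
#'   range.
#' @export
gaussian_smooth <- function(signal, kernel = default_kernel(trace_fs(signal))) {
  if (!inherits(kernel, "gaussian_kernel")) {
    abort("kernel must be a gaussian_kernel", class = "gaitbouts_error_parameter")
  }
  x <- signal$value
  n <- length(x)
  if (kernel$window_samples > n) {
    abort("kernel window is longer than the signal",
          class = "gaitbouts_error_parameter")
  }
  half <- (kernel$window_samples - 1L) / 2L
  w <- kernel$weights
  if (half == 0L) return(activity_signal(x, trace_fs(signal)))
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), w, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), w, sides = 2)
  idx <- (half + 1L):(half + n)
  activity_signal(as.numeric(num[idx] / den[idx]), trace_fs(signal))
}
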