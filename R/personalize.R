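#' Personalized activity threshold from a 24-h trace
#'
#' The per-wearer activity threshold is the median of the detrended 3D
#' magnitude over a 24-h free-living period.  Because a wearer is stationary
#' far more often than in movement, the daily median tracks the baseline of
#' no movement for that person and sensor.  The median is taken on the
#' detrended magnitude — the same signal the threshold is applied to
#' downstream — since a raw-magnitude median (~1 g, gravity) could not serve
#' as an activity threshold.
#'
#' @param day_trace An [accel_trace()] spanning roughly one day of wear.
#' @param min_hours Minimum required span in hours (default 20, tolerating
#'   minor data loss on a nominal 24-h day).
#' @param cutoff_hz,order Detrending parameters, matching the detector's.
#' @return An object of class `personal_threshold`: list with `value_g`,
#'   `n_samples_used` and `hours`.  `value_g` must fall in the sanity band
#'   (0, 0.5) g; values outside raise a calibration-quality error.
#' @export
personal_threshold <- function(day_trace, min_hours = 20,
                               cutoff_hz = 0.25, order = 4L) {
  fs <- trace_fs(day_trace)
  hours <- nrow(day_trace) / fs / 3600
  if (hours < min_hours - 1 / 3600) {
    abort(sprintf("insufficient calibration data: %.2f h < %g h required",
                  hours, min_hours),
          class = "gaitbouts_error_calibration_short")
  }
  mag <- magnitude3d(detrend(day_trace, cutoff_hz = cutoff_hz, order = order))
  value <- median(mag$value)
  if (!(value > 0 && value < 0.5)) {
    abort(sprintf("calibration quality: median %.4f g outside the (0, 0.5) g sanity band",
                  value),
          class = "gaitbouts_error_calibration_quality")
  }
  structure(
    list(value_g = value, n_samples_used = nrow(day_trace), hours = hours),
    class = "personal_threshold"
  )
}

#' @export
print.personal_threshold <- function(x, ...) {
  cat(sprintf("<personal_threshold> %.4f g (median of detrended 3D magnitude, %.1f h, %d samples)\n",
              x$value_g, x$hours, x$n_samples_used))
  invisible(x)
}

#' Tidy a personal threshold
#' @param x A `personal_threshold`.
#' @param ... Unused.
#' @return One-row tibble with `value_g`, `n_samples_used`, `hours`.
#' @export
tidy.personal_threshold <- function(x, ...) {
  tibble(value_g = x$value_g, n_samples_used = x$n_samples_used,
         hours = x$hours)
}

#' Build a personalized detector configuration, with a generic fallback
#'
#' Runs [personal_threshold()] on a calibration day and returns the matching
#' [detector_config()] (personalized mode: the derived threshold and a
#' 100-frame minimum gap).  If calibration fails its sanity checks and
#' `fallback = TRUE`, a warning is emitted and the generic configuration
#' (0.05 g, 50 frames) is returned instead — calibration failure never
#' silently changes semantics.
#'
#' @param day_trace An [accel_trace()] of the calibration day.
#' @param fallback Fall back to the generic configuration on calibration
#'   failure instead of raising.
#' @param min_hours Passed to [personal_threshold()].
#' @param ... Further arguments to [detector_config()].
#' @return A `detector_config`.
#' @export
personalized_config <- function(day_trace, fallback = FALSE, min_hours = 20,
                                ...) {
  pt <- tryCatch(
    personal_threshold(day_trace, min_hours = min_hours),
    error = function(e) {
      if (!fallback) stop(e)
      warn(paste0("calibration failed (", conditionMessage(e),
                  "); falling back to the generic configuration"))
      NULL
    }
  )
  if (is.null(pt)) return(detector_config(mode = "generic", ...))
  detector_config(mode = "personalized",
                  activity_threshold_g = pt$value_g, ...)
}

#' Extract one 24-h calibration day from a multi-day trace
#'
#' Day boundaries are wear-time relative (hours since recording start), not
#' calendar midnights: `day_index = 2` returns hours \[48, 72) of wear, the
#' third day — typically chosen because wearers have acclimated to the
#' sensor by then and early-wear data loss has passed.
#'
#' @param week_trace An [accel_trace()] spanning multiple days.
#' @param day_index 0-based day to extract.
#' @return The 24-h (or remaining, if shorter) sub-trace as an
#'   `accel_trace`.
#' @export
choose_calibration_day <- function(week_trace, day_index) {
  fs <- trace_fs(week_trace)
  n <- nrow(week_trace)
  day_frames <- round(24 * 3600 * fs)
  start <- day_index * day_frames
  if (day_index < 0 || start >= n) {
    abort(sprintf("day_index %d is beyond the recording (%.2f days)",
                  day_index, n / day_frames),
          class = "gaitbouts_error_range")
  }
  end <- min(n, start + day_frames)
  idx <- (start + 1L):end
  accel_trace(week_trace$ax[idx], week_trace$ay[idx], week_trace$az[idx],
              fs = fs, t0 = attr(week_trace, "t0"))
}
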