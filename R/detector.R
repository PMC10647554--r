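#' Detector configuration
#'
#' Bundles every threshold of the staged walking-bout classifier.  The
#' generic mode uses a global 0.05 g activity threshold and a 50-frame
#' minimum gap; the personalized mode replaces the threshold with the
#' median-derived per-wearer value and raises the minimum gap to 100 frames.
#' Frame counts are stated at the nominal 100 Hz and rescaled by `fs/100`
#' at run time.
#'
#' @param mode `"generic"` or `"personalized"`.
#' @param activity_threshold_g Activity threshold in g applied to the
#'   detrended 3D magnitude.  Defaults to 0.05 g in generic mode; must be
#'   supplied (normally from [personal_threshold()]) in personalized mode.
#' @param likelihood_threshold Dimensionless threshold in (0, 1) on the
#'   smoothed binary activity-likelihood signal (default 0.2).
#' @param min_gap_frames Minimum number of low-likelihood samples a gap must
#'   contain to be kept as genuine non-activity, in frames at 100 Hz
#'   (default 50 generic, 100 personalized).
#' @param heuristic_threshold_g High-intensity threshold in g on the smoothed
#'   magnitude used to reject sit-stand-like transients (default 0.4 g).
#' @param heuristic_fraction Maximum fraction of a bout's samples allowed
#'   above the heuristic threshold for it to count as walking (default 0.025).
#' @param min_bout_seconds Minimum walking-bout duration in seconds
#'   (default 2).
#' @param cutoff_hz,filter_order Detrending low-pass parameters.
#' @param kernel_window_s,kernel_sigma_divisor Gaussian smoothing window in
#'   seconds and the window/sigma ratio.
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(mode = c("generic", "personalized"),
                            activity_threshold_g = NULL,
                            likelihood_threshold = 0.2,
                            min_gap_frames = NULL,
                            heuristic_threshold_g = 0.4,
                            heuristic_fraction = 0.025,
                            min_bout_seconds = 2,
                            cutoff_hz = 0.25,
                            filter_order = 4L,
                            kernel_window_s = 2,
                            kernel_sigma_divisor = 20) {
  mode <- match.arg(mode)
  if (is.null(activity_threshold_g)) {
    if (mode == "personalized") {
      abort("personalized mode needs activity_threshold_g (see personal_threshold)",
            class = "gaitbouts_error_parameter")
    }
    activity_threshold_g <- 0.05
  }
  if (is.null(min_gap_frames)) {
    min_gap_frames <- if (mode == "generic") 50L else 100L
  }
  if (likelihood_threshold <= 0 || likelihood_threshold >= 1) {
    abort("likelihood_threshold must lie in (0, 1)",
          class = "gaitbouts_error_parameter")
  }
  if (!(heuristic_threshold_g > activity_threshold_g &&
        activity_threshold_g > 0)) {
    abort("need heuristic_threshold_g > activity_threshold_g > 0",
          class = "gaitbouts_error_parameter")
  }
  if (min_gap_frames < 1L || min_bout_seconds <= 0 || heuristic_fraction <= 0) {
    abort("min_gap_frames, min_bout_seconds, heuristic_fraction must be positive",
          class = "gaitbouts_error_parameter")
  }
  structure(
    list(mode = mode,
         activity_threshold_g = activity_threshold_g,
         likelihood_threshold = likelihood_threshold,
         min_gap_frames = as.integer(min_gap_frames),
         heuristic_threshold_g = heuristic_threshold_g,
         heuristic_fraction = heuristic_fraction,
         min_bout_seconds = min_bout_seconds,
         cutoff_hz = cutoff_hz,
         filter_order = as.integer(filter_order),
         kernel_window_s = kernel_window_s,
         kernel_sigma_divisor = kernel_sigma_divisor),
    class = "detector_config"
  )
}

# frame-count parameters are nominal at 100 Hz
scale_frames <- function(frames, fs) max(1L, as.integer(round(frames * fs / 100)))

new_bout_set <- function(start_frame, end_frame, kind, n, fs,
                         boundary = NULL) {
  out <- tibble(start_frame = as.integer(start_frame),
                end_frame = as.integer(end_frame),
                kind = as.character(kind))
  if (!is.null(boundary)) out$boundary <- boundary
  if (nrow(out) > 0L) {
    if (any(out$end_frame <= out$start_frame) || any(out$start_frame < 0L) ||
        any(out$end_frame > n)) {
      abort("invalid bout interval", class = "gaitbouts_error_bouts")
    }
    if (is.unsorted(out$start_frame, strictly = TRUE) ||
        any(out$start_frame[-1] < out$end_frame[-nrow(out)])) {
      abort("bouts must be sorted and pairwise disjoint",
            class = "gaitbouts_error_bouts")
    }
  }
  attr(out, "n") <- as.integer(n)
  attr(out, "fs") <- as.numeric(fs)
  class(out) <- c("bout_set", class(out))
  out
}

#' Threshold a signal into a binary activity series
#'
#' A sample is active (label 1) iff its value is strictly above the
#' threshold; a value exactly at the threshold counts as inactive, keeping
#' the rule conservative toward non-walking.
#'
#' @param signal An [activity_signal()] (the detrended 3D magnitude).
#' @param threshold_g Positive threshold in the signal's units.
#' @return A [label_series()].
#' @export
binarize <- function(signal, threshold_g) {
  if (!is.numeric(threshold_g) || threshold_g <= 0) {
    abort("threshold_g must be positive", class = "gaitbouts_error_parameter")
  }
  label_series(as.integer(signal$value > threshold_g), trace_fs(signal))
}

#' Find gaps (maximal runs of non-activity) in a binary series
#'
#' @param labels A [label_series()].
#' @return A `bout_set` of half-open `[start_frame, end_frame)` intervals of
#'   kind `"gap"`, with a `boundary` column flagging gaps that touch either
#'   end of the recording.
#' @export
find_gaps <- function(labels) {
  lv <- labels$label
  n <- length(lv)
  r <- rle(lv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 0L
  new_bout_set(starts[keep], ends[keep], rep("gap", sum(keep)),
               n = n, fs = trace_fs(labels),
               boundary = (starts[keep] == 0L) | (ends[keep] == n))
}

#' Filter gaps by activity likelihood, returning activity bouts
#'
#' For each interior gap, the number of samples whose activity likelihood is
#' below `likelihood_threshold` is compared to the minimum gap threshold.
#' Gaps with at least `min_gap_frames` low-likelihood samples are retained as
#' genuine non-activity; shorter dips are absorbed into the surrounding
#' activity.  Gaps touching either end of the recording are always retained,
#' since no surrounding activity exists to absorb them.  The complement of
#' the retained gaps is returned as activity bouts.
#'
#' @param gaps A `bout_set` from [find_gaps()].
#' @param likelihood The smoothed binary signal (an [activity_signal()] with
#'   values in \[0, 1\]).
#' @param config A [detector_config()].
#' @return A `bout_set` of kind `"activity"`.
#' @export
filter_gaps <- function(gaps, likelihood, config = detector_config()) {
  lik <- likelihood$value
  if (any(lik < 0 | lik > 1)) {
    abort("likelihood values must lie in [0, 1]",
          class = "gaitbouts_error_contract")
  }
  n <- attr(gaps, "n")
  fs <- attr(gaps, "fs")
  if (length(lik) != n) {
    abort("likelihood length does not match the gap set",
          class = "gaitbouts_error_alignment")
  }
  min_gap <- scale_frames(config$min_gap_frames, fs)
  retained <- purrr::pmap_lgl(
    gaps[, c("start_frame", "end_frame", "boundary")],
    function(start_frame, end_frame, boundary) {
      if (boundary) return(TRUE)
      idx <- (start_frame + 1L):end_frame
      sum(lik[idx] < config$likelihood_threshold) >= min_gap
    }
  )
  # complement of retained gaps = activity
  starts <- integer(0); ends <- integer(0); cur <- 0L
  gs <- gaps$start_frame[retained]; ge <- gaps$end_frame[retained]
  for (i in seq_along(gs)) {
    if (gs[i] > cur) { starts <- c(starts, cur); ends <- c(ends, gs[i]) }
    cur <- ge[i]
  }
  if (cur < n) { starts <- c(starts, cur); ends <- c(ends, n) }
  new_bout_set(starts, ends, rep("activity", length(starts)), n = n, fs = fs)
}

#' Reject high-intensity activity bouts (sit-stand transients)
#'
#' Within each activity bout the fraction of samples whose smoothed 3D
#' magnitude exceeds the heuristic threshold (0.4 g) is computed.  The bout
#' is kept as walking iff that fraction is strictly below
#' `heuristic_fraction` (2.5%); otherwise it is marked
#' `"rejected_transition"`.  Transitions between sitting and standing incur
#' high linear accelerations that walking at everyday speeds does not.
#'
#' @param bouts A `bout_set` of activity bouts.
#' @param smoothed_mag The Gaussian-smoothed detrended magnitude
#'   (an [activity_signal()], units g).
#' @param config A [detector_config()].
#' @return A `bout_set` with kinds `"walking"` and `"rejected_transition"`.
#' @export
reject_transitions <- function(bouts, smoothed_mag,
                               config = detector_config()) {
  sm <- smoothed_mag$value
  if (length(sm) != attr(bouts, "n")) {
    abort("smoothed magnitude length does not match the bout set",
          class = "gaitbouts_error_alignment")
  }
  if (nrow(bouts) > 0L && any(bouts$end_frame == bouts$start_frame)) {
    abort("empty bout", class = "gaitbouts_error_contract")
  }
  kind <- purrr::map2_chr(bouts$start_frame, bouts$end_frame, function(s, e) {
    frac <- mean(sm[(s + 1L):e] > config$heuristic_threshold_g)
    if (frac < config$heuristic_fraction) "walking" else "rejected_transition"
  })
  new_bout_set(bouts$start_frame, bouts$end_frame, kind,
               n = attr(bouts, "n"), fs = attr(bouts, "fs"))
}

#' Enforce the minimum walking-bout duration
#'
#' Walking bouts shorter than `min_bout_seconds` (default 2 s) are marked
#' `"rejected_short"`; a bout of exactly the minimum duration is kept.
#'
#' @param bouts A `bout_set` from [reject_transitions()].
#' @param config A [detector_config()].
#' @return A `bout_set` with short walking bouts re-kinded.
#' @export
enforce_min_duration <- function(bouts, config = detector_config()) {
  fs <- attr(bouts, "fs")
  kind <- bouts$kind
  short <- kind == "walking" &
    (bouts$end_frame - bouts$start_frame) / fs < config$min_bout_seconds
  kind[short] <- "rejected_short"
  new_bout_set(bouts$start_frame, bouts$end_frame, kind,
               n = attr(bouts, "n"), fs = fs)
}

#' Convert between bout sets and per-sample label series
#'
#' The two representations are interchangeable: `bouts_to_labels()` marks
#' samples inside bouts of the requested kinds with 1, and
#' `labels_to_bouts()` extracts maximal runs of 1s.  Round-tripping is
#' lossless.
#'
#' @param bouts A `bout_set`.
#' @param kinds Character vector of bout kinds to mark as 1.
#' @param labels A [label_series()].
#' @param kind Kind to assign to extracted bouts.
#' @return A [label_series()] / a `bout_set`.
#' @export
bouts_to_labels <- function(bouts, kinds = "walking") {
  lv <- integer(attr(bouts, "n"))
  sel <- bouts$kind %in% kinds
  for (i in which(sel)) {
    lv[(bouts$start_frame[i] + 1L):bouts$end_frame[i]] <- 1L
  }
  label_series(lv, attr(bouts, "fs"))
}

#' @rdname bouts_to_labels
#' @export
labels_to_bouts <- function(labels, kind = "walking") {
  r <- rle(labels$label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == 1L
  new_bout_set(starts[keep], ends[keep], rep(kind, sum(keep)),
               n = length(labels$label), fs = trace_fs(labels))
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(paste0("[", stage, "] ", conditionMessage(e)),
            class = "gaitbouts_error_stage", parent = e)
    }
  )
}

#' Detect walking bouts in a raw acceleration trace
#'
#' Runs the full staged pipeline: detrend each axis (zero-phase Butterworth),
#' take the 3D magnitude, binarize against the activity threshold, smooth the
#' binary series into an activity likelihood, find and filter gaps, reject
#' high-intensity transients against the smoothed magnitude, and enforce the
#' minimum bout duration.  The pipeline is deterministic and
#' orientation-independent.
#'
#' @param trace An [accel_trace()].
#' @param config A [detector_config()]; generic defaults if omitted.
#' @return An object of class `walk_detection`: a list with `bouts` (all
#'   bouts, rejected ones retained with their rejection kind for audit),
#'   `labels` (per-sample walking labels built from the surviving walking
#'   bouts only), `magnitude` (detrended 3D magnitude), `config`, `fs`, `n`.
#'   Use [tidy()] for the bout table, [glance()] for a one-row summary and
#'   [autoplot()] for a diagnostic plot.
#' @examples
#' spec <- corridor_protocol(seed = 7)
#' sim <- build_scenario(spec)
#' fit <- detect_walking(sim$trace)
#' glance(fit)
#' @export
detect_walking <- function(trace, config = detector_config()) {
  fs <- trace_fs(trace)
  kernel <- default_kernel(fs, config$kernel_window_s,
                           config$kernel_sigma_divisor)
  detrended <- with_stage("detrend",
    detrend(trace, config$cutoff_hz, config$filter_order))
  mag <- with_stage("magnitude", magnitude3d(detrended))
  binary <- with_stage("binarize",
    binarize(mag, config$activity_threshold_g))
  likelihood <- with_stage("likelihood_smooth",
    gaussian_smooth(activity_signal(binary$label, fs), kernel))
  gaps <- with_stage("find_gaps", find_gaps(binary))
  activity <- with_stage("filter_gaps", filter_gaps(gaps, likelihood, config))
  smoothed_mag <- with_stage("magnitude_smooth", gaussian_smooth(mag, kernel))
  classified <- with_stage("reject_transitions",
    reject_transitions(activity, smoothed_mag, config))
  final <- with_stage("enforce_min_duration",
    enforce_min_duration(classified, config))
  structure(
    list(bouts = final,
         labels = bouts_to_labels(final, kinds = "walking"),
         magnitude = mag,
         config = config,
         fs = fs,
         n = nrow(trace)),
    class = "walk_detection"
  )
}

#' @export
print.walk_detection <- function(x, ...) {
  g <- glance(x)
  cat("<walk_detection> ", x$config$mode, " mode, ",
      x$n, " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  walking bouts: ", g$n_walking_bouts,
      " (", sprintf("%.1f", g$walking_seconds), " s, ",
      sprintf("%.1f%%", 100 * g$walking_fraction), " of trace)\n", sep = "")
  cat("  rejected: ", g$n_rejected_transition, " transition, ",
      g$n_rejected_short, " short\n", sep = "")
  invisible(x)
}

#' Tidy the bouts of a walking-bout detection
#'
#' @param x A `walk_detection` object.
#' @param ... Unused.
#' @return A tibble with one row per bout: `start_frame`, `end_frame`
#'   (half-open, 0-based), `start_s`, `duration_s`, `kind`.
#' @export
tidy.walk_detection <- function(x, ...) {
  fs <- x$fs
  as_tibble(x$bouts) |>
    dplyr::mutate(start_s = .data$start_frame / fs,
                  duration_s = (.data$end_frame - .data$start_frame) / fs)
}

#' One-row summary of a walking-bout detection
#'
#' @param x A `walk_detection` object.
#' @param ... Unused.
#' @return A one-row tibble: bout counts by kind, walking seconds and the
#'   walking fraction of the trace.
#' @export
glance.walk_detection <- function(x, ...) {
  b <- x$bouts
  walk <- b[b$kind == "walking", ]
  tibble(
    n_walking_bouts = nrow(walk),
    n_rejected_transition = sum(b$kind == "rejected_transition"),
    n_rejected_short = sum(b$kind == "rejected_short"),
    walking_seconds = sum(walk$end_frame - walk$start_frame) / x$fs,
    walking_fraction = sum(walk$end_frame - walk$start_frame) / x$n,
    mode = x$config$mode,
    activity_threshold_g = x$config$activity_threshold_g
  )
}
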