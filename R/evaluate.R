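#' Per-sample confusion counts between predicted and true labels
#'
#' @param pred,truth [label_series()] objects (or plain 0/1 vectors) of equal
#'   length; 1 = walking.
#' @return A one-row tibble of class `confusion_counts`: `tp`, `tn`, `fp`,
#'   `fn`, summing to the number of compared samples.
#' @export
confusion_counts <- function(pred, truth) {
  p <- if (is.data.frame(pred)) pred$label else as.integer(pred)
  t_ <- if (is.data.frame(truth)) truth$label else as.integer(truth)
  if (length(p) != length(t_)) {
    abort(sprintf("label streams differ in length (%d vs %d)",
                  length(p), length(t_)),
          class = "gaitbouts_error_alignment")
  }
  if (is.data.frame(pred) && is.data.frame(truth) &&
      abs(trace_fs(pred) - trace_fs(truth)) > 1e-9) {
    abort("label streams differ in sampling rate",
          class = "gaitbouts_error_alignment")
  }
  out <- tibble(
    tp = sum(p == 1L & t_ == 1L),
    tn = sum(p == 0L & t_ == 0L),
    fp = sum(p == 1L & t_ == 0L),
    fn = sum(p == 0L & t_ == 1L)
  )
  class(out) <- c("confusion_counts", class(out))
  out
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' The six binary-classifier metrics from confusion counts
#'
#' Sensitivity (true positive rate), specificity (true negative rate),
#' precision (positive predictive value), negative predictive value,
#' accuracy and F1 score.  A metric whose denominator is zero is undefined
#' and reported as `NA`, never silently as 0; an undefined precision or
#' sensitivity propagates to an undefined F1.
#'
#' @param counts A [confusion_counts()] row (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @param participant_id Optional identifier carried into the report.
#' @return A one-row tibble: the counts, the six metrics, `participant_id`.
#' @examples
#' classification_metrics(list(tp = 8, fn = 2, tn = 7, fp = 3))
#' @export
classification_metrics <- function(counts, participant_id = NA_character_) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) {
    abort("no samples to compare", class = "gaitbouts_error_empty")
  }
  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  prec <- safe_ratio(tp, tp + fp)
  npv  <- safe_ratio(tn, tn + fn)
  acc  <- (tp + tn) / total
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  tibble(participant_id = as.character(participant_id),
         tp = tp, tn = tn, fp = fp, fn = fn,
         sensitivity = sens, specificity = spec, precision = prec,
         npv = npv, accuracy = acc, f1 = f1)
}

#' Evaluate a detection against ground truth
#'
#' Convenience wrapper: per-sample confusion counts followed by
#' [classification_metrics()].
#'
#' @param pred A `walk_detection` object or a [label_series()].
#' @param truth A [label_series()] of ground-truth walking labels.
#' @param participant_id Optional identifier.
#' @return A one-row metrics tibble.
#' @export
evaluate_detection <- function(pred, truth, participant_id = NA_character_) {
  if (inherits(pred, "walk_detection")) pred <- pred$labels
  classification_metrics(confusion_counts(pred, truth), participant_id)
}

#' Average evaluation metrics across participants
#'
#' Unweighted per-metric mean and standard deviation (n - 1 denominator)
#' over participants, so trial duration does not enter and every participant
#' weighs equally.  Undefined (`NA`) entries are skipped and counted.
#'
#' @param reports A tibble of per-participant metric rows
#'   (from [evaluate_detection()] / [classification_metrics()]).
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`, `n`,
#'   `n_undefined`.
#' @export
cohort_average <- function(reports) {
  if (!is.data.frame(reports) || nrow(reports) == 0L) {
    abort("need at least one participant report", class = "gaitbouts_error_empty")
  }
  metric_cols <- c("sensitivity", "specificity", "precision", "npv",
                   "accuracy", "f1")
  reports |>
    dplyr::select(dplyr::all_of(metric_cols)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric") |>
    dplyr::mutate(metric = factor(.data$metric, levels = metric_cols)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = if (sum(!is.na(.data$value)) > 0)
        mean(.data$value, na.rm = TRUE) else NA_real_,
      sd = if (sum(!is.na(.data$value)) > 1)
        sd(.data$value, na.rm = TRUE) else NA_real_,
      n = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(metric = as.character(.data$metric))
}

#' Wall-clock processing time per 10 min of data
#'
#' Times [detect_walking()] on a trace, averages over `repeats` runs, and
#' normalizes to milliseconds per 6000 frames (10 min at 100 Hz).  Reported
#' for information only: the figure is hardware-dependent.
#'
#' @param trace An [accel_trace()].
#' @param config A [detector_config()].
#' @param repeats Number of timed runs to average (>= 1).
#' @return Milliseconds per 6000 frames (a positive scalar).
#' @export
timing_per_block <- function(trace, config = detector_config(), repeats = 3L) {
  if (repeats < 1L) {
    abort("repeats must be >= 1", class = "gaitbouts_error_parameter")
  }
  elapsed <- vapply(seq_len(repeats), function(i) {
    unname(system.time(detect_walking(trace, config))["elapsed"])
  }, numeric(1))
  mean(elapsed) / nrow(trace) * 6000 * 1000
}
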