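# Delimited-text readers and writers -----------------------------------------
#
# All writers are deterministic (stable column order, fixed float
# formatting), so outputs are diffable across runs.  Sampling rates travel
# in a leading "# fs=<Hz>" comment line; readers take the rate from that
# header first, then from a time column, then from the fs argument.

guess_delim <- function(path) {
  first <- readr::read_lines(path, n_max = 10)
  first <- first[!startsWith(first, "#")]
  if (length(first) == 0L) return(",")
  if (grepl("\t", first[1])) "\t" else ","
}

header_fs <- function(path) {
  top <- readr::read_lines(path, n_max = 5)
  m <- grep("^#\\s*fs\\s*[=:]", top, value = TRUE)
  if (length(m) == 0L) return(NULL)
  as.numeric(sub("^#\\s*fs\\s*[=:]\\s*", "", m[1]))
}

read_table_flex <- function(path, delim = NULL, col_names = TRUE) {
  delim <- delim %||% guess_delim(path)
  readr::read_delim(path, delim = delim, comment = "#",
                    col_names = col_names, show_col_types = FALSE,
                    progress = FALSE)
}

repair_axis <- function(x, fs, axis) {
  bad <- !is.finite(x)
  if (!any(bad)) return(x)
  r <- rle(bad)
  if (any(r$lengths[r$values] >= fs)) {
    abort(sprintf("gap of >= 1 s of non-finite samples on axis %s; cannot repair",
                  axis),
          class = "gaitbouts_error_parse")
  }
  if (bad[1] || bad[length(x)]) {
    abort(sprintf("non-finite samples at the edge of the recording on axis %s",
                  axis),
          class = "gaitbouts_error_parse")
  }
  idx <- seq_along(x)
  x[bad] <- stats::approx(idx[!bad], x[!bad], xout = idx[bad])$y
  x
}

#' Read a triaxial acceleration trace from delimited text
#'
#' Accepts comma- or tab-separated text (optionally gzip-compressed, read
#' transparently) with three acceleration columns in g and an optional time
#' column in seconds.  Column names are configurable; without a header the
#' columns are taken as (time,) ax, ay, az by position.  The sampling rate
#' is resolved, in order of precedence, from a `# fs=<Hz>` header comment,
#' from the time column spacing, or from the `fs` argument.
#'
#' @param path File path (`.gz` allowed).
#' @param fs Fallback sampling rate in Hz.
#' @param col_names Optional named character vector mapping `time`, `ax`,
#'   `ay`, `az` to the file's column names.
#' @param delim Field delimiter; guessed (comma vs tab) if `NULL`.
#' @param repair If `TRUE`, non-finite samples in gaps shorter than 1 s are
#'   linearly interpolated; longer gaps error.  If `FALSE` (default), any
#'   non-finite sample errors, naming the first offending row.
#' @return An [accel_trace()].
#' @export
read_accel_trace <- function(path, fs = NULL, col_names = NULL, delim = NULL,
                             repair = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gaitbouts_error_usage")
  }
  hfs <- header_fs(path)
  df <- read_table_flex(path, delim)
  headered <- !all(grepl("^[-+0-9.eE]+$",
                         sub("\\.\\.\\.[0-9]+$", "", names(df))))
  if (!headered) {
    df <- read_table_flex(path, delim, col_names = FALSE)
    names(df) <- if (ncol(df) >= 4L) c("time", "ax", "ay", "az")[seq_len(ncol(df))] else
      c("ax", "ay", "az")[seq_len(ncol(df))]
  }
  if (!is.null(col_names)) {
    for (std in names(col_names)) {
      if (!col_names[[std]] %in% names(df)) {
        abort(paste0("column not found: ", col_names[[std]]),
              class = "gaitbouts_error_parse")
      }
      names(df)[names(df) == col_names[[std]]] <- std
    }
  }
  lowered <- tolower(names(df))
  names(df)[lowered %in% c("x", "accx", "acc_x")] <- "ax"
  names(df)[lowered %in% c("y", "accy", "acc_y")] <- "ay"
  names(df)[lowered %in% c("z", "accz", "acc_z")] <- "az"
  names(df)[lowered %in% c("t", "timestamp", "seconds")] <- "time"
  if (!all(c("ax", "ay", "az") %in% names(df))) {
    abort("could not identify the ax, ay, az columns",
          class = "gaitbouts_error_parse")
  }
  fs_use <- hfs %||%
    (if ("time" %in% names(df) && nrow(df) > 1L) {
      dt <- diff(df$time)
      if (any(dt <= 0) || max(dt) - min(dt) > 0.01 * median(dt)) NULL else
        1 / median(dt)
    } else NULL) %||% fs
  if (is.null(fs_use)) {
    abort("sampling rate unavailable: no header, regular time column, or fs argument",
          class = "gaitbouts_error_parse")
  }
  if (repair) {
    for (axis in c("ax", "ay", "az")) {
      df[[axis]] <- repair_axis(df[[axis]], fs_use, axis)
    }
  } else {
    bad <- which(!is.finite(df$ax) | !is.finite(df$ay) | !is.finite(df$az))
    if (length(bad) > 0L) {
      abort(paste0("non-finite acceleration at data row ", bad[1],
                   " (use repair = TRUE to interpolate short gaps)"),
            class = "gaitbouts_error_parse")
    }
  }
  accel_trace(df$ax, df$ay, df$az, fs = fs_use)
}

#' Write a trace to CSV
#'
#' @param trace An [accel_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_lines(sprintf("# fs=%.10g", trace_fs(trace)), path)
  readr::write_csv(as_tibble(trace)[, c("time", "ax", "ay", "az")], path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write per-sample binary label streams
#'
#' Label files hold one `label` column of 0/1 values (plus the `# fs=`
#' header); any other value is a parse error.  Writing then reading
#' reproduces the series exactly.
#'
#' @param path File path.
#' @param fs Fallback sampling rate in Hz if the file has no header.
#' @param labels A [label_series()].
#' @return A [label_series()] / `path` invisibly.
#' @export
read_labels <- function(path, fs = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gaitbouts_error_usage")
  }
  fs_use <- header_fs(path) %||% fs
  if (is.null(fs_use)) {
    abort("sampling rate unavailable for label file",
          class = "gaitbouts_error_parse")
  }
  df <- read_table_flex(path)
  col <- if ("label" %in% names(df)) df$label else df[[ncol(df)]]
  if (any(!col %in% c(0, 1))) {
    abort("label values outside {0, 1}", class = "gaitbouts_error_parse")
  }
  label_series(as.integer(col), fs_use)
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  readr::write_lines(sprintf("# fs=%.10g", trace_fs(labels)), path)
  readr::write_csv(tibble(label = labels$label), path,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write bout tables
#'
#' Bout files carry `participant_id`, `start_frame`, `end_frame` (0-based,
#' half-open), `start_time` and `duration_s` in seconds (fixed 3-decimal
#' formatting), and `kind`; the trace length and rate travel in header
#' comments so a written set reads back identically.
#'
#' @param bouts A `bout_set` (or a `walk_detection`, whose bouts are taken).
#' @param path File path.
#' @param participant_id Identifier written with every row.
#' @return A `bout_set` / `path` invisibly.
#' @export
write_bouts <- function(bouts, path, participant_id = NA_character_) {
  if (inherits(bouts, "walk_detection")) bouts <- bouts$bouts
  fs <- attr(bouts, "fs")
  out <- tibble(
    participant_id = as.character(participant_id),
    start_frame = bouts$start_frame,
    end_frame = bouts$end_frame,
    start_time = sprintf("%.3f", bouts$start_frame / fs),
    duration_s = sprintf("%.3f", (bouts$end_frame - bouts$start_frame) / fs),
    kind = bouts$kind
  )
  readr::write_lines(sprintf("# fs=%.10g", fs), path)
  readr::write_lines(sprintf("# n=%d", attr(bouts, "n")), path, append = TRUE)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_bouts
#' @export
read_bouts <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gaitbouts_error_usage")
  }
  top <- readr::read_lines(path, n_max = 5)
  fs <- header_fs(path)
  nm <- grep("^#\\s*n\\s*[=:]", top, value = TRUE)
  if (is.null(fs) || length(nm) == 0L) {
    abort("bout file is missing its # fs= / # n= header",
          class = "gaitbouts_error_parse")
  }
  n <- as.integer(sub("^#\\s*n\\s*[=:]\\s*", "", nm[1]))
  df <- read_table_flex(path)
  new_bout_set(df$start_frame, df$end_frame, df$kind, n = n, fs = fs)
}

#' Write an evaluation report to CSV
#'
#' @param report A metrics tibble ([classification_metrics()] rows or a
#'   [cohort_average()] table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}

#' Read / write a personalized calibration record
#'
#' A small JSON record (`value_g`, `n_samples_used`, `hours`) produced by
#' `calibrate` and consumed by `detect --mode personalized`.
#'
#' @param pt A `personal_threshold`.
#' @param path File path.
#' @return A `personal_threshold` / `path` invisibly.
#' @export
write_calibration <- function(pt, path) {
  jsonlite::write_json(unclass(pt), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gaitbouts_error_usage")
  }
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(value_g = rec$value_g,
                 n_samples_used = rec$n_samples_used,
                 hours = rec$hours),
            class = "personal_threshold")
}

#' Load a detector configuration from a YAML file
#'
#' The file holds any subset of [detector_config()]'s arguments as top-level
#' keys; omitted keys keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... Overrides applied after the file (e.g. `mode`,
#'   `activity_threshold_g` from a calibration record).
#' @return A `detector_config`.
#' @export
read_detector_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  allowed <- names(formals(detector_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    abort(paste0("unknown configuration key(s): ",
                 paste(unknown, collapse = ", ")),
          class = "gaitbouts_error_parse")
  }
  do.call(detector_config, vals)
}

#' Read a simulation scenario from a YAML file
#'
#' Expected keys: `fs`, `noise_sigma_g`, `seed`, optional `orientation`
#' (either a 9-element row-major matrix or `roll`/`pitch`/`yaw` radians),
#' and `segments`, a list of maps each with `kind`, `duration_s` and
#' generator parameters.
#'
#' @param path YAML file path.
#' @return A [scenario_spec()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "gaitbouts_error_usage")
  }
  y <- yaml::read_yaml(path)
  orientation <- diag(3)
  if (!is.null(y$orientation)) {
    o <- y$orientation
    orientation <- if (is.list(o) && any(c("roll", "pitch", "yaw") %in% names(o))) {
      euler_rotation(o$roll %||% 0, o$pitch %||% 0, o$yaw %||% 0)
    } else {
      matrix(as.numeric(unlist(o)), 3, 3, byrow = TRUE)
    }
  }
  segments <- purrr::map(y$segments, function(s) {
    if (!is.null(s$pauses)) {
      s$pauses <- purrr::map(s$pauses, as.numeric)
    }
    s
  })
  scenario_spec(segments, fs = y$fs %||% 100,
                noise_sigma_g = y$noise_sigma_g %||% 0.008,
                orientation = orientation, seed = y$seed %||% 1L)
}
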