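# Domain types shared across the package. All times are minutes from record
# start; undefined fiducials are NA.

#' Five warning-category labels, in display order
#'
#' @return Character vector `c("False", "Early", "On Time", "Late", "Missed")`.
#' @export
warning_categories <- function() {
  c("False", "Early", "On Time", "Late", "Missed")
}

#' Framework configuration
#'
#' Bundles the parameters that define the timeliness window and the alarm
#' strategies. `t_min`/`t_max` bound the interval before the event in which a
#' warning counts as On Time: a lead time `T_WARNING = time_event -
#' time_warning` is On Time when `t_max > T_WARNING >= t_min`. `t_min` may be
#' zero or negative (a warning after the event can still be actionable in some
#' applications).
#'
#' @param t_min Minimum actionable lead time before the event, minutes.
#' @param t_max Maximum meaningful lead time before the event, minutes.
#' @param threshold Warning threshold on the normalized indicator, in \[0, 1\].
#'   The warning state is on while the indicator is `>= threshold`.
#' @param off_delay Latch off-delay for the STAY-ON strategy, minutes: once on,
#'   the warning stays on until the indicator has been below threshold for at
#'   least this long.
#' @param sample_interval Spacing of the uniform time grid, minutes.
#' @return An object of class `framework_config`.
#' @examples
#' framework_config()            # case-study defaults: 1, 14, 0.9, 10
#' framework_config(t_min = 0, t_max = 30)
#' @export
framework_config <- function(t_min = 1, t_max = 14, threshold = 0.9,
                             off_delay = 10, sample_interval = 1) {
  stopifnot(is.numeric(t_min), length(t_min) == 1L, is.finite(t_min),
            is.numeric(t_max), length(t_max) == 1L, is.finite(t_max),
            is.numeric(threshold), length(threshold) == 1L,
            is.numeric(off_delay), length(off_delay) == 1L,
            is.numeric(sample_interval), length(sample_interval) == 1L)
  if (t_max <= t_min) {
    stop("`t_max` (", t_max, ") must be greater than `t_min` (", t_min, ")",
         call. = FALSE)
  }
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1], got ", threshold, call. = FALSE)
  }
  if (off_delay < 0) stop("`off_delay` must be >= 0", call. = FALSE)
  if (sample_interval <= 0) {
    stop("`sample_interval` must be > 0", call. = FALSE)
  }
  structure(
    list(t_min = as.numeric(t_min), t_max = as.numeric(t_max),
         threshold = as.numeric(threshold), off_delay = as.numeric(off_delay),
         sample_interval = as.numeric(sample_interval)),
    class = "framework_config"
  )
}

#' @export
print.framework_config <- function(x, ...) {
  cat("Framework configuration\n")
  cat(sprintf("  On-Time window : t_max > T_WARNING >= t_min with t_min = %g, t_max = %g min\n",
              x$t_min, x$t_max))
  cat(sprintf("  threshold      : indicator >= %g\n", x$threshold))
  cat(sprintf("  off_delay      : %g min (STAY-ON latch)\n", x$off_delay))
  cat(sprintf("  sample_interval: %g min\n", x$sample_interval))
  invisible(x)
}

#' Monitored record: uniformly sampled vital-sign traces
#'
#' One subject's heart rate (HR, beats/min), systolic blood pressure (SBP,
#' mmHg) and optionally mean arterial pressure (MAP, mmHg) on a uniform time
#' grid, plus an optional critical-event time annotation and the baseline
#' window used to fit population baseline statistics. Non-event (control)
#' records have `event_time = NA`.
#'
#' @param record_id Record identifier, a single string.
#' @param times Sample timestamps in minutes from record start; strictly
#'   increasing and uniformly spaced.
#' @param hr Heart rate, beats/min; positive where defined.
#' @param sbp Systolic blood pressure, mmHg; positive where defined.
#' @param map Mean arterial pressure, mmHg, or `NULL` when unavailable.
#' @param record_type `"event"` or `"nonevent"`. Defaults to `"event"` when
#'   `event_time` is defined, `"nonevent"` otherwise.
#' @param event_time Time of the critical event in minutes, or `NA` for a
#'   non-event record. Must lie within the sampled span.
#' @param baseline_window Half-open interval `c(start, end)` in minutes marking
#'   the pre-event baseline period, or `NULL`.
#' @param tol Relative tolerance on sampling uniformity.
#' @return An object of class `record_series`.
#' @export
record_series <- function(record_id, times, hr, sbp, map = NULL,
                          record_type = NULL, event_time = NA_real_,
                          baseline_window = NULL, tol = 1e-6) {
  stopifnot(is.character(record_id), length(record_id) == 1L,
            nzchar(record_id))
  times <- as.numeric(times)
  n <- length(times)
  if (n < 2L) {
    stop("record ", record_id, ": needs at least 2 samples", call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("record ", record_id, ": times must be strictly increasing",
         call. = FALSE)
  }
  step <- stats::median(dt)
  if (any(abs(dt - step) > tol * max(step, 1))) {
    stop("record ", record_id, ": nonuniform sampling (expected step ",
         signif(step, 6), " min)", call. = FALSE)
  }
  for (nm in c("hr", "sbp")) {
    v <- get(nm)
    if (length(v) != n) {
      stop("record ", record_id, ": `", nm, "` length ", length(v),
           " != ", n, " samples", call. = FALSE)
    }
    if (any(v <= 0, na.rm = TRUE)) {
      stop("record ", record_id, ": `", nm, "` must be positive where defined",
           call. = FALSE)
    }
  }
  if (!is.null(map) && length(map) != n) {
    stop("record ", record_id, ": `map` length mismatch", call. = FALSE)
  }
  event_time <- as.numeric(event_time)
  stopifnot(length(event_time) == 1L)
  if (!is.na(event_time) &&
      (event_time < times[1L] || event_time > times[n])) {
    stop("record ", record_id, ": event_time ", event_time,
         " outside record span [", times[1L], ", ", times[n], "]",
         call. = FALSE)
  }
  if (is.null(record_type)) {
    record_type <- if (is.na(event_time)) "nonevent" else "event"
  }
  record_type <- match.arg(record_type, c("event", "nonevent"))
  if (record_type == "nonevent" && !is.na(event_time)) {
    stop("record ", record_id,
         ": nonevent record cannot carry an event_time", call. = FALSE)
  }
  if (record_type == "event" && is.na(event_time)) {
    stop("record ", record_id, ": event record needs a defined event_time",
         call. = FALSE)
  }
  if (!is.null(baseline_window)) {
    baseline_window <- as.numeric(baseline_window)
    stopifnot(length(baseline_window) == 2L)
    if (baseline_window[2L] <= baseline_window[1L]) {
      stop("record ", record_id, ": baseline_window must be a nonempty ",
           "interval", call. = FALSE)
    }
    if (!is.na(event_time) && baseline_window[2L] > event_time) {
      stop("record ", record_id, ": baseline_window must precede event_time",
           call. = FALSE)
    }
  }
  structure(
    list(record_id = record_id, times = times,
         hr = as.numeric(hr), sbp = as.numeric(sbp),
         map = if (is.null(map)) NULL else as.numeric(map),
         record_type = record_type, event_time = event_time,
         baseline_window = baseline_window, sample_interval = step),
    class = "record_series"
  )
}

#' @export
print.record_series <- function(x, ...) {
  cat(sprintf("<record_series %s> %s, %d samples @ %g min, span [%g, %g] min\n",
              x$record_id, x$record_type, length(x$times), x$sample_interval,
              x$times[1L], x$times[length(x$times)]))
  if (!is.na(x$event_time)) cat(sprintf("  event_time: %g min\n", x$event_time))
  invisible(x)
}

#' Binary warning trace aligned to a record's time grid
#'
#' @param record_id Record identifier.
#' @param times Sample timestamps, minutes.
#' @param state Integer 0/1 vector, same length as `times`; 1 means a warning
#'   is active at that sample.
#' @return An object of class `warning_trace`.
#' @export
warning_trace <- function(record_id, times, state) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  times <- as.numeric(times)
  state <- as.integer(state)
  if (length(state) != length(times)) {
    stop("trace ", record_id, ": state/times length mismatch", call. = FALSE)
  }
  if (!all(state %in% c(0L, 1L))) {
    stop("trace ", record_id, ": state values must be 0 or 1", call. = FALSE)
  }
  structure(list(record_id = record_id, times = times, state = state),
            class = "warning_trace")
}

#' Fiducial table: one row per warning or per warningless record
#'
#' The sufficient input for the whole framework. Each warning contributes one
#' row with its onset (`time_warning_min`); each record that raised no warning
#' contributes one row with `time_warning_min = NA` so that record rosters and
#' warning lists live in a single table. Non-event records always have
#' `time_event_min = NA`; event records always have it defined.
#'
#' @param record_id Character vector of record identifiers.
#' @param record_type `"event"` or `"nonevent"`, per row.
#' @param time_event_min Event time in minutes, `NA` for non-event rows.
#' @param time_warning_min Warning onset in minutes, `NA` for a warningless
#'   record's roster row.
#' @return A `data.frame` with class `fiducial_table` prepended.
#' @export
fiducial_table <- function(record_id = character(),
                           record_type = character(),
                           time_event_min = numeric(),
                           time_warning_min = numeric()) {
  df <- data.frame(record_id = as.character(record_id),
                   record_type = as.character(record_type),
                   time_event_min = as.numeric(time_event_min),
                   time_warning_min = as.numeric(time_warning_min),
                   stringsAsFactors = FALSE)
  validate_fiducial_table(df)
}

#' Coerce and validate a data frame as a fiducial table
#'
#' @param df Data frame with the [fiducial_table()] columns.
#' @return The validated `fiducial_table`.
#' @export
as_fiducial_table <- function(df) {
  validate_fiducial_table(as.data.frame(df))
}

validate_fiducial_table <- function(df) {
  req <- c("record_id", "record_type", "time_event_min", "time_warning_min")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("fiducial table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_type <- !df$record_type %in% c("event", "nonevent")
  if (any(bad_type)) {
    stop("invalid record_type value(s): ",
         paste(unique(df$record_type[bad_type]), collapse = ", "),
         call. = FALSE)
  }
  ne_with_event <- df$record_type == "nonevent" & !is.na(df$time_event_min)
  if (any(ne_with_event)) {
    stop("nonevent record(s) with defined time_event_min: ",
         paste(unique(df$record_id[ne_with_event]), collapse = ", "),
         call. = FALSE)
  }
  ev_without_event <- df$record_type == "event" & is.na(df$time_event_min)
  if (any(ev_without_event)) {
    stop("event record(s) with undefined time_event_min: ",
         paste(unique(df$record_id[ev_without_event]), collapse = ", "),
         call. = FALSE)
  }
  both <- intersect(df$record_id[df$record_type == "event"],
                    df$record_id[df$record_type == "nonevent"])
  if (length(both)) {
    stop("record id(s) appear under both record types: ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  # one event time per record
  ev <- df[df$record_type == "event", , drop = FALSE]
  if (nrow(ev)) {
    per <- tapply(ev$time_event_min, ev$record_id,
                  function(v) length(unique(v)))
    if (any(per > 1L)) {
      stop("record(s) with more than one event time: ",
           paste(names(per)[per > 1L], collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- unique(c("fiducial_table", class(df)))
  df
}

#' Bin counts: the sufficient statistic for both profiles
#'
#' Tallies of warnings by category plus record denominators. `total_warnings`
#' counts actual warnings only (False + Early + On Time + Late); Missed rows
#' are events without a warning, not warnings, and are excluded from the total.
#'
#' @param n_false,n_early,n_on_time,n_late Warning tallies per category.
#' @param n_missed Number of event records with no warning.
#' @param n_event_records,n_nonevent_records Distinct record counts by type.
#' @return An object of class `bin_counts`.
#' @export
bin_counts <- function(n_false = 0L, n_early = 0L, n_on_time = 0L,
                       n_late = 0L, n_missed = 0L,
                       n_event_records = 0L, n_nonevent_records = 0L) {
  v <- c(n_false = n_false, n_early = n_early, n_on_time = n_on_time,
         n_late = n_late, n_missed = n_missed,
         n_event_records = n_event_records,
         n_nonevent_records = n_nonevent_records)
  if (any(v < 0) || any(v != floor(v))) {
    stop("bin counts must be nonnegative integers", call. = FALSE)
  }
  if (n_missed > n_event_records) {
    stop("n_missed (", n_missed, ") cannot exceed n_event_records (",
         n_event_records, ")", call. = FALSE)
  }
  structure(
    list(n_false = as.integer(n_false), n_early = as.integer(n_early),
         n_on_time = as.integer(n_on_time), n_late = as.integer(n_late),
         n_missed = as.integer(n_missed),
         n_event_records = as.integer(n_event_records),
         n_nonevent_records = as.integer(n_nonevent_records),
         total_warnings = as.integer(n_false + n_early + n_on_time + n_late)),
    class = "bin_counts"
  )
}

#' @export
print.bin_counts <- function(x, ...) {
  cat("Warning bin counts\n")
  tab <- c(x$n_false, x$n_early, x$n_on_time, x$n_late, x$n_missed)
  names(tab) <- warning_categories()
  print(tab)
  cat(sprintf("  total warnings: %d | records: %d event, %d non-event\n",
              x$total_warnings, x$n_event_records, x$n_nonevent_records))
  invisible(x)
}
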