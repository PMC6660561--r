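# Alarm strategies: turn an indicator series into binary warning traces, and
# decompose traces into warning episodes.

#' RESPONSIVE strategy: direct thresholding
#'
#' The warning state is a straight binary interpretation of the indicator:
#' on at every sample where `si_norm >= threshold`, off elsewhere. The
#' boundary is inclusive (a sample exactly at threshold raises a warning).
#'
#' @param si_norm Normalized indicator values in \[0, 1\].
#' @param times Sample timestamps, minutes.
#' @param threshold Warning threshold; defaults to 0.9.
#' @param record_id Record identifier carried on the returned trace.
#' @return A [warning_trace()].
#' @export
responsive <- function(si_norm, times, threshold = 0.9,
                       record_id = "record") {
  if (length(si_norm) != length(times)) {
    stop("`si_norm` and `times` must have the same length", call. = FALSE)
  }
  warning_trace(record_id, times,
                as.integer(!is.na(si_norm) & si_norm >= threshold))
}

#' STAY-ON strategy: latch with an off-delay
#'
#' Once on, the warning remains on until the input state has been
#' continuously off for at least `off_delay` minutes. On the sampled grid the
#' quiet time between two on-episodes is the time from the last active sample
#' of one to the first active sample of the next; a gap with quiet time
#' shorter than `off_delay` is filled with 1s, merging the episodes. A
#' trailing 0-run whose duration (to the last sample) is shorter than
#' `off_delay` keeps the latch on to the end of the record, because the
#' turn-off condition was never met. Leading 0s are untouched.
#' `off_delay = 0` is the identity, and the operation is idempotent.
#'
#' @param trace A [warning_trace()] from e.g. [responsive()].
#' @param off_delay Off-delay in minutes.
#' @param sample_interval Grid spacing in minutes; defaults to the spacing
#'   inferred from `trace$times`.
#' @return A [warning_trace()] with `state >= trace$state` elementwise.
#' @export
stay_on <- function(trace, off_delay, sample_interval = NULL) {
  stopifnot(inherits(trace, "warning_trace"), off_delay >= 0)
  n <- length(trace$state)
  if (is.null(sample_interval)) {
    sample_interval <- if (n >= 2L) stats::median(diff(trace$times)) else 1
  }
  if (off_delay == 0 || !any(trace$state == 1L)) return(trace)
  runs <- rle(trace$state)
  state <- trace$state
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seen_on <- FALSE
  n_runs <- length(runs$lengths)
  for (k in seq_len(n_runs)) {
    if (runs$values[k] == 1L) { seen_on <- TRUE; next }
    if (!seen_on) next                       # leading zeros: latch never armed
    # interior gap: quiet time runs to the next onset, one step past the run;
    # trailing gap: quiet time runs to the last observed sample
    gap_min <- (runs$lengths[k] + (k < n_runs)) * sample_interval
    if (gap_min < off_delay) state[starts[k]:ends[k]] <- 1L
  }
  warning_trace(trace$record_id, trace$times, state)
}

#' Extract warning episodes from a binary trace
#'
#' Decomposes the trace into maximal runs of 1s. The onset of each episode is
#' the timestamp of its first active sample — this is the warning-onset
#' fiducial the framework consumes — and the offset is the timestamp of its
#' last active sample.
#'
#' @param trace A [warning_trace()].
#' @return A data frame with columns `record_id`, `onset`, `offset`, one row
#'   per episode, ordered by onset; zero rows for an all-quiet trace.
#' @export
extract_episodes <- function(trace) {
  stopifnot(inherits(trace, "warning_trace"))
  runs <- rle(trace$state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- runs$values == 1L
  data.frame(record_id = rep(trace$record_id, sum(on)),
             onset = trace$times[starts[on]],
             offset = trace$times[ends[on]],
             stringsAsFactors = FALSE)
}

#' Run a named strategy over a cohort of records
#'
#' Computes SI_NORM for every record (using baseline statistics fitted to the
#' cohort's event records), thresholds it, and optionally latches it.
#'
#' @param records Named list of [record_series()] objects.
#' @param config A [framework_config()].
#' @param strategy `"responsive"` or `"stay_on"`.
#' @param stats Optional pre-fitted `baseline_stats`; fitted from `records`
#'   when `NULL`.
#' @return Named list of [warning_trace()] objects, one per record.
#' @export
apply_strategy <- function(records, config,
                           strategy = c("responsive", "stay_on"),
                           stats = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(config, "framework_config"))
  if (is.null(stats)) stats <- fit_baseline_stats(records)
  traces <- lapply(records, function(r) {
    si_norm <- normalize_si(shock_index(r$hr, r$sbp), stats)
    tr <- responsive(si_norm, r$times, config$threshold, r$record_id)
    if (strategy == "stay_on") {
      tr <- stay_on(tr, config$off_delay, config$sample_interval)
    }
    tr
  })
  names(traces) <- names(records)
  traces
}
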