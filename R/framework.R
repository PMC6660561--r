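# The core method: fiducial extraction, five-bin categorization, the two
# normalized performance profiles, and traditional per-record metrics.

#' Build a fiducial table from warning episodes and record annotations
#'
#' Each warning episode contributes one row carrying its onset as
#' `time_warning_min` and the record's event time (or `NA` on non-event
#' records); each record with zero episodes contributes one roster row with
#' `time_warning_min = NA`, so a single table carries both the per-warning
#' list and the per-record denominators. Records whose lengths differ by more
#' than `length_ratio_warn` emit a warning: profiles computed from records of
#' very different lengths can be misleading.
#'
#' @param episodes Data frame of episodes (`record_id`, `onset`, ...) as
#'   produced by [extract_episodes()] (rows from several records may be
#'   concatenated), or a list of per-record episode data frames.
#' @param records Named list of [record_series()] objects covering every
#'   `record_id` in `episodes`.
#' @param length_ratio_warn Warn when max/min record duration exceeds this
#'   factor; `Inf` disables the check.
#' @return A [fiducial_table()].
#' @export
build_fiducials <- function(episodes, records, length_ratio_warn = 2) {
  if (is.list(episodes) && !is.data.frame(episodes)) {
    episodes <- do.call(rbind, episodes)
  }
  if (is.null(episodes) || nrow(episodes) == 0L) {
    episodes <- data.frame(record_id = character(), onset = numeric())
  }
  ids <- vapply(records, `[[`, "", "record_id")
  unknown <- setdiff(unique(episodes$record_id), ids)
  if (length(unknown)) {
    stop("episode(s) reference unknown record(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  spans <- vapply(records, function(r) diff(range(r$times)), 0)
  if (length(spans) >= 2L && is.finite(length_ratio_warn) &&
      max(spans) > length_ratio_warn * min(spans)) {
    warning("record lengths differ by more than ", length_ratio_warn,
            "x (", min(spans), " to ", max(spans), " min); ",
            "profiles may be misleading", call. = FALSE)
  }
  rows <- lapply(records, function(r) {
    ep <- episodes[episodes$record_id == r$record_id, , drop = FALSE]
    tw <- if (nrow(ep)) sort(ep$onset) else NA_real_
    data.frame(record_id = r$record_id, record_type = r$record_type,
               time_event_min = r$event_time, time_warning_min = tw,
               stringsAsFactors = FALSE)
  })
  validate_fiducial_table(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Categorize fiducial rows into the five warning bins
#'
#' The lead time of a warning is `T_WARNING = time_event - time_warning`.
#' Rules, applied per row:
#' \itemize{
#'   \item False: a warning on a non-event record (event time undefined);
#'   \item Early: event-record warning with `T_WARNING >= t_max`;
#'   \item On Time: event-record warning with `t_max > T_WARNING >= t_min`;
#'   \item Late: event-record warning with `T_WARNING < t_min` — including
#'     onsets after the event (negative lead), since `t_min` itself may be
#'     zero or negative;
#'   \item Missed: an event record with no warning (onset undefined).
#' }
#' Only the onset matters: an episode that starts Early and persists into the
#' On-Time window is still Early. A non-event roster row with no warning is
#' not categorizable (`NA`); it contributes only to record counts.
#'
#' @param rows A [fiducial_table()] (or data frame with its columns).
#' @param config A [framework_config()].
#' @return Character vector, one of `"False"`, `"Early"`, `"On Time"`,
#'   `"Late"`, `"Missed"`, or `NA` for warningless non-event rows.
#' @export
categorize <- function(rows, config) {
  stopifnot(inherits(config, "framework_config"))
  rows <- validate_fiducial_table(as.data.frame(rows))
  n <- nrow(rows)
  out <- rep(NA_character_, n)
  if (n == 0L) return(out)
  is_event <- rows$record_type == "event"
  has_warning <- !is.na(rows$time_warning_min)
  out[!is_event & has_warning] <- "False"
  out[is_event & !has_warning] <- "Missed"
  ew <- is_event & has_warning
  lead <- rows$time_event_min[ew] - rows$time_warning_min[ew]
  out[ew] <- ifelse(lead >= config$t_max, "Early",
                    ifelse(lead >= config$t_min, "On Time", "Late"))
  out
}

#' Tally fiducial rows into bin counts
#'
#' Record denominators are the distinct `record_id`s per record type —
#' warningless roster rows count toward the denominators without contributing
#' a warning. `total_warnings` excludes Missed.
#'
#' @param rows A [fiducial_table()].
#' @param config A [framework_config()].
#' @return A [bin_counts()] object.
#' @export
count_bins <- function(rows, config) {
  rows <- validate_fiducial_table(as.data.frame(rows))
  cat_ <- categorize(rows, config)
  tab <- table(factor(cat_, levels = warning_categories()))
  bin_counts(
    n_false = tab[["False"]], n_early = tab[["Early"]],
    n_on_time = tab[["On Time"]], n_late = tab[["Late"]],
    n_missed = tab[["Missed"]],
    n_event_records =
      length(unique(rows$record_id[rows$record_type == "event"])),
    n_nonevent_records =
      length(unique(rows$record_id[rows$record_type == "nonevent"]))
  )
}

#' Time profile of warning proportions (per-warning unit of analysis)
#'
#' Each of the five tallies — including Missed, which is not itself a
#' warning — is divided by the total number of warnings
#' (False + Early + On Time + Late). The four warning bins therefore sum to
#' exactly 1; adding Missed can push the total above 1. This profile
#' estimates the probability that a critical event occurs in the actionable
#' window when a warning is given (analogous to positive predictive value).
#'
#' @param counts A [bin_counts()] object.
#' @return Named numeric vector over [warning_categories()].
#' @export
warning_proportions <- function(counts) {
  stopifnot(inherits(counts, "bin_counts"))
  if (counts$total_warnings == 0L) {
    stop("warning proportions are undefined: zero warnings", call. = FALSE)
  }
  stats::setNames(
    c(counts$n_false, counts$n_early, counts$n_on_time, counts$n_late,
      counts$n_missed) / counts$total_warnings,
    warning_categories()
  )
}

#' Time profile of warnings per record (per-record unit of analysis)
#'
#' The False tally is divided by the number of non-event records; Early,
#' On Time, Late and Missed are divided by the number of event records.
#' Values are unbounded above — a sum across the four event-side bins greater
#' than 1 reveals warning burden (multiple warnings per event). A bin whose
#' denominator is zero is an error when its numerator is nonzero; a 0/0 bin
#' is reported as 0 and flagged in the `"undefined_bins"` attribute.
#'
#' @param counts A [bin_counts()] object.
#' @return Named numeric vector over [warning_categories()], with an
#'   `undefined_bins` attribute naming any 0/0 bins.
#' @export
warnings_per_record <- function(counts) {
  stopifnot(inherits(counts, "bin_counts"))
  num <- c(counts$n_false, counts$n_early, counts$n_on_time, counts$n_late,
           counts$n_missed)
  den <- c(counts$n_nonevent_records, rep(counts$n_event_records, 4L))
  names(num) <- warning_categories()
  bad <- den == 0L & num > 0L
  if (any(bad)) {
    stop("zero record denominator with nonzero warnings in bin(s): ",
         paste(names(num)[bad], collapse = ", "), call. = FALSE)
  }
  undef <- den == 0L & num == 0L
  out <- ifelse(den == 0L, 0, num / den)
  names(out) <- warning_categories()
  if (any(undef)) attr(out, "undefined_bins") <- names(out)[undef]
  out
}

#' Traditional per-record performance metrics
#'
#' Treats each record as a single positive/negative. An event record is a
#' true positive when its warning state is on at any sample whose lead time
#' `time_event - t` falls in the actionable window (`t_max > lead >= t_min` —
#' the same half-open convention as the bins, so any-active-sample-in-window
#' can credit records whose warning onset was Early). A non-event record with
#' at least one active sample anywhere is a single false positive. Then
#' `PPV = 100 TP / (TP + FP)`, `sensitivity = 100 TP / n_event_records`, and
#' `false positive rate = 100 FP / n_nonevent_records` (= 1 - specificity).
#'
#' @param traces Named list of [warning_trace()] objects, one per record.
#' @param records Named list of [record_series()] objects.
#' @param config A [framework_config()].
#' @return Object of class `traditional_metrics` with components
#'   `n_true_positive_records`, `n_false_positive_records`,
#'   `n_event_records`, `n_nonevent_records`, `ppv`, `sensitivity`,
#'   `false_positive_rate` (percent; `ppv` is `NA` when `TP + FP = 0`).
#' @export
traditional_metrics <- function(traces, records, config) {
  stopifnot(inherits(config, "framework_config"))
  trace_ids <- vapply(traces, `[[`, "", "record_id")
  rec_ids <- vapply(records, `[[`, "", "record_id")
  if (!setequal(trace_ids, rec_ids) || length(traces) != length(records)) {
    stop("traces and records must cover the same record ids", call. = FALSE)
  }
  traces <- traces[match(rec_ids, trace_ids)]
  tp <- 0L; fp <- 0L; n_ev <- 0L; n_ne <- 0L
  for (i in seq_along(records)) {
    r <- records[[i]]; tr <- traces[[i]]
    if (length(tr$state) != length(r$times)) {
      stop("trace/record grid mismatch for record ", r$record_id,
           call. = FALSE)
    }
    if (r$record_type == "event") {
      n_ev <- n_ev + 1L
      lead <- r$event_time - r$times
      in_window <- lead < config$t_max & lead >= config$t_min
      if (any(tr$state == 1L & in_window)) tp <- tp + 1L
    } else {
      n_ne <- n_ne + 1L
      if (any(tr$state == 1L)) fp <- fp + 1L
    }
  }
  structure(
    list(n_true_positive_records = tp, n_false_positive_records = fp,
         n_event_records = n_ev, n_nonevent_records = n_ne,
         ppv = if (tp + fp > 0L) 100 * tp / (tp + fp) else NA_real_,
         sensitivity = if (n_ev > 0L) 100 * tp / n_ev else NA_real_,
         false_positive_rate = if (n_ne > 0L) 100 * fp / n_ne else NA_real_),
    class = "traditional_metrics"
  )
}

#' @export
print.traditional_metrics <- function(x, ...) {
  cat("Traditional per-record metrics\n")
  cat(sprintf("  PPV                : %s (%d/%d)\n",
              if (is.na(x$ppv)) "undefined" else
                sprintf("%.1f%%", x$ppv),
              x$n_true_positive_records,
              x$n_true_positive_records + x$n_false_positive_records))
  cat(sprintf("  Sensitivity        : %s (%d/%d)\n",
              if (is.na(x$sensitivity)) "undefined" else
                sprintf("%.1f%%", x$sensitivity),
              x$n_true_positive_records, x$n_event_records))
  cat(sprintf("  False positive rate: %s (%d/%d)\n",
              if (is.na(x$false_positive_rate)) "undefined" else
                sprintf("%.1f%%", x$false_positive_rate),
              x$n_false_positive_records, x$n_nonevent_records))
  invisible(x)
}

#' Both normalized profiles from bin counts
#'
#' @param counts A [bin_counts()] object.
#' @return Object of class `profile_pair`: `warning_proportions` and
#'   `warnings_per_record`, each a named 5-vector.
#' @export
profile_pair <- function(counts) {
  structure(list(warning_proportions = warning_proportions(counts),
                 warnings_per_record = warnings_per_record(counts)),
            class = "profile_pair")
}

#' @export
print.profile_pair <- function(x, ...) {
  m <- rbind(`warning proportion` = round(x$warning_proportions, 2),
             `warnings per record` = round(x$warnings_per_record, 2))
  print(m)
  invisible(x)
}

#' End-to-end characterization of one or more strategies on a cohort
#'
#' Runs indicator -> strategy -> fiducials -> bins -> profiles plus
#' traditional metrics for each requested strategy, sharing one baseline fit.
#'
#' @param records Named list of [record_series()] objects.
#' @param config A [framework_config()].
#' @param strategies Character vector among `"responsive"`, `"stay_on"`.
#' @return Named list (per strategy) of lists with elements `traces`,
#'   `fiducials`, `counts`, `profiles`, `metrics`.
#' @export
characterize <- function(records, config,
                         strategies = c("responsive", "stay_on")) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  stats <- fit_baseline_stats(records)
  out <- lapply(strategies, function(s) {
    traces <- apply_strategy(records, config, s, stats = stats)
    episodes <- do.call(rbind, lapply(traces, extract_episodes))
    fid <- build_fiducials(episodes, records, length_ratio_warn = Inf)
    counts <- count_bins(fid, config)
    list(traces = traces, fiducials = fid, counts = counts,
         profiles = if (counts$total_warnings > 0L) profile_pair(counts)
                    else NULL,
         metrics = traditional_metrics(traces, records, config))
  })
  names(out) <- strategies
  out
}
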