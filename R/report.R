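# Rendering of the two 5-bin profile charts and tabular/JSON summaries.

profile_barplot <- function(values, main, ylab, ylim_cap) {
  graphics::barplot(as.numeric(values), names.arg = names(values),
                    main = main, ylab = ylab,
                    ylim = c(0, ylim_cap), col = "grey40", border = NA,
                    cex.names = 0.8)
  graphics::box()
}

render_one <- function(values, path, main, ylab, ylim_cap, format) {
  open_dev <- switch(format,
    svg = function(p) grDevices::svg(p, width = 6, height = 4),
    png = function(p) grDevices::png(p, width = 900, height = 600, res = 150)
  )
  open_dev(path)
  on.exit(grDevices::dev.off())
  profile_barplot(values, main, ylab, ylim_cap)
}

#' Render the two profile charts per strategy
#'
#' For every strategy, writes one bar chart of the warning-proportion profile
#' and one of the warnings-per-record profile, bins in the order False,
#' Early, On Time, Late, Missed. The proportion chart's y-axis tops out at
#' `max(1, tallest bin)`; the per-record chart is not clamped, since warning
#' burden can exceed 1. Output is deterministic for fixed inputs.
#'
#' @param profiles Named list (strategy name -> `profile_pair`).
#' @param path Output directory (created if needed).
#' @param format `"svg"` (default) or `"png"`.
#' @return Invisibly, the vector of written file paths.
#' @export
render_profiles <- function(profiles, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (length(profiles) == 0L) {
    stop("no strategies to render", call. = FALSE)
  }
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("`profiles` must be a named list keyed by strategy", call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(profiles)) {
    pp <- profiles[[nm]]
    wp <- pp$warning_proportions
    wr <- pp$warnings_per_record
    f1 <- file.path(path, sprintf("%s_warning_proportions.%s", nm, format))
    f2 <- file.path(path, sprintf("%s_warnings_per_record.%s", nm, format))
    render_one(wp, f1, sprintf("%s: warning proportions", toupper(nm)),
               "proportion of all warnings", max(1, max(wp)), format)
    render_one(wr, f2, sprintf("%s: warnings per record", toupper(nm)),
               "warnings per record", max(1, max(wr)) * 1.05, format)
    files <- c(files, f1, f2)
  }
  invisible(files)
}

#' Write tidy CSV and JSON summaries for one or more strategies
#'
#' The CSV has one row per strategy and category with the warning tally,
#' total warnings, record denominator, and both profile values at full
#' precision. The JSON adds the traditional per-record metrics. Strategies
#' with zero warnings get `NA` proportions and an `undefined_proportions`
#' flag instead of an error.
#'
#' @param counts Named list (strategy -> [bin_counts()]).
#' @param profiles Named list (strategy -> `profile_pair`), same keys.
#' @param metrics Optional named list (strategy -> `traditional_metrics`),
#'   same keys.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary as a list.
#' @export
write_summary <- function(counts, profiles, metrics = NULL,
                          csv_path = NULL, json_path = NULL) {
  keys <- names(counts)
  if (!identical(sort(keys), sort(names(profiles))) ||
      (!is.null(metrics) && !identical(sort(keys), sort(names(metrics))))) {
    stop("`counts`, `profiles` and `metrics` must share the same strategy ",
         "keys", call. = FALSE)
  }
  cats <- warning_categories()
  tidy <- do.call(rbind, lapply(keys, function(k) {
    ct <- counts[[k]]
    tallies <- c(ct$n_false, ct$n_early, ct$n_on_time, ct$n_late,
                 ct$n_missed)
    denom <- c(ct$n_nonevent_records, rep(ct$n_event_records, 4L))
    pp <- profiles[[k]]
    data.frame(strategy = k, category = cats, n_warnings = tallies,
               total_warnings = ct$total_warnings, n_records = denom,
               warning_proportion =
                 if (is.null(pp)) NA_real_ else
                   as.numeric(pp$warning_proportions),
               warnings_per_record =
                 if (is.null(pp)) NA_real_ else
                   as.numeric(pp$warnings_per_record),
               stringsAsFactors = FALSE)
  }))
  summary_list <- lapply(keys, function(k) {
    ct <- counts[[k]]
    pp <- profiles[[k]]
    out <- list(
      counts = list(False = ct$n_false, Early = ct$n_early,
                    `On Time` = ct$n_on_time, Late = ct$n_late,
                    Missed = ct$n_missed,
                    total_warnings = ct$total_warnings,
                    n_event_records = ct$n_event_records,
                    n_nonevent_records = ct$n_nonevent_records),
      undefined_proportions = is.null(pp)
    )
    if (!is.null(pp)) {
      out$warning_proportions <- as.list(pp$warning_proportions)
      out$warnings_per_record <- as.list(pp$warnings_per_record)
    }
    if (!is.null(metrics)) {
      m <- metrics[[k]]
      out$traditional_metrics <- list(
        n_true_positive_records = m$n_true_positive_records,
        n_false_positive_records = m$n_false_positive_records,
        ppv = m$ppv, sensitivity = m$sensitivity,
        false_positive_rate = m$false_positive_rate
      )
    }
    out
  })
  names(summary_list) <- keys
  if (!is.null(csv_path)) {
    utils::write.csv(tidy, csv_path, row.names = FALSE, na = "NA",
                     quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary_list, json_path, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(summary_list)
}
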