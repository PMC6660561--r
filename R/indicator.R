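# Shock Index and its population-baseline CDF normalization.

#' Shock Index
#'
#' Elementwise ratio of heart rate to systolic blood pressure, the classic
#' bedside indicator of circulatory shock (values near 1 or above suggest
#' hemodynamic compromise).
#'
#' @param hr Heart rate, beats/min.
#' @param sbp Systolic blood pressure, mmHg; must be positive.
#' @return Numeric vector `hr / sbp`, unitless.
#' @examples
#' shock_index(c(90, 120), c(120, 80))  # 0.75, 1.5
#' @export
shock_index <- function(hr, sbp) {
  if (length(hr) != length(sbp)) {
    stop("`hr` and `sbp` must have the same length", call. = FALSE)
  }
  bad <- which(!is.na(sbp) & sbp <= 0)
  if (length(bad)) {
    stop("non-positive SBP at sample index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  as.numeric(hr) / as.numeric(sbp)
}

#' Population baseline statistics of the Shock Index
#'
#' Pools the shock-index samples falling inside each event record's baseline
#' window and returns their mean and sample standard deviation (n - 1
#' denominator). Only event records contribute — the normalization is
#' anchored to the event population's resting physiology — so non-event
#' records in `records` are ignored.
#'
#' @param records List of [record_series()] objects; event records must carry
#'   a `baseline_window`.
#' @return Object of class `baseline_stats`: `mean`, `sd`, `n_samples`.
#' @export
fit_baseline_stats <- function(records) {
  if (inherits(records, "record_series")) records <- list(records)
  pooled <- unlist(lapply(records, function(r) {
    if (r$record_type != "event") return(numeric())
    if (is.null(r$baseline_window)) {
      stop("event record ", r$record_id, " has no baseline_window",
           call. = FALSE)
    }
    keep <- r$times >= r$baseline_window[1L] & r$times < r$baseline_window[2L]
    shock_index(r$hr[keep], r$sbp[keep])
  }), use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) < 2L) {
    stop("fewer than 2 pooled baseline samples (got ", length(pooled), ")",
         call. = FALSE)
  }
  s <- stats::sd(pooled)
  if (!is.finite(s) || s == 0) {
    stop("degenerate baseline: pooled shock-index standard deviation is zero",
         call. = FALSE)
  }
  structure(list(mean = mean(pooled), sd = s, n_samples = length(pooled)),
            class = "baseline_stats")
}

#' @export
print.baseline_stats <- function(x, ...) {
  cat(sprintf("<baseline_stats> mean %.4f, sd %.4f (%d pooled samples)\n",
              x$mean, x$sd, x$n_samples))
  invisible(x)
}

#' Normalized Shock Index (SI_NORM)
#'
#' Maps raw shock-index values onto a 0-1 scale through the cumulative
#' distribution function of a normal distribution parameterized by the
#' population baseline mean and standard deviation: `pnorm(si, mean, sd)`.
#' A value of 0.5 means "at the baseline mean"; values near 1 mean far above
#' resting physiology.
#'
#' @param si Shock-index values.
#' @param stats A `baseline_stats` object from [fit_baseline_stats()], or any
#'   list with `mean` and `sd` components (`sd > 0`).
#' @return Numeric vector strictly inside (0, 1).
#' @export
normalize_si <- function(si, stats) {
  if (is.null(stats$mean) || is.null(stats$sd) || stats$sd <= 0) {
    stop("`stats` must provide `mean` and positive `sd`", call. = FALSE)
  }
  stats::pnorm(as.numeric(si), mean = stats$mean, sd = stats$sd)
}
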