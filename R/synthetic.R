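# Synthetic cohort generation: noisy vital-sign records emulating a
# hemorrhage-to-hypotension protocol (event records) and stable baseline
# segments (non-event records), plus exact-count warning fixtures for testing
# the framework end to end.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default generator settings for synthetic vital-sign records
#'
#' Event records start from stable baseline vitals, then HR rises while SBP
#' and MAP fall linearly (emulating progressive hemorrhage) with additive
#' Gaussian noise per channel per sample; the critical event is the first
#' sample where MAP has dropped at least `map_drop` below the configured
#' baseline MAP. Non-event records are stationary noise around baseline
#' means for `nonevent_duration` minutes (2 h, approximating the longest
#' event records). The non-event HR mean sits slightly below the event
#' baseline so control records cross the warning threshold only occasionally.
#'
#' @param hr_mean,sbp_mean,map_mean Baseline means: beats/min, mmHg, mmHg.
#' @param hr_sd,sbp_sd,map_sd Additive noise standard deviations per channel.
#' @param hr_drift Post-baseline HR slope, beats/min per min (rising).
#' @param sbp_drift,map_drift Post-baseline downward slopes, mmHg per min
#'   (positive numbers; subtracted).
#' @param baseline_duration Pre-drift baseline length, min.
#' @param duration Total event-record length, min.
#' @param nonevent_duration Non-event record length, min (default 120).
#' @param nonevent_hr_mean Non-event HR mean, beats/min.
#' @param map_drop MAP drop from baseline defining the event, mmHg.
#' @param sample_interval Grid spacing, min.
#' @return A list of generator settings.
#' @export
generator_params <- function(hr_mean = 80, sbp_mean = 120, map_mean = 90,
                             hr_sd = 5, sbp_sd = 8, map_sd = 4,
                             hr_drift = 1, sbp_drift = 0.75, map_drift = 1,
                             baseline_duration = 30, duration = 120,
                             nonevent_duration = 120, nonevent_hr_mean = 74,
                             map_drop = 30, sample_interval = 1) {
  as.list(environment())
}

#' Generate a synthetic event record
#'
#' MAP starts at baseline and drifts down until it has dropped `map_drop`
#' mmHg below the baseline mean; the first such sample defines the record's
#' event time. HR rises and SBP falls over the same drift phase, so the shock
#' index climbs ahead of the event. With zero noise the event time equals the
#' closed-form crossing `baseline_duration + map_drop / map_drift`.
#'
#' @param params Settings from [generator_params()].
#' @param seed Integer seed; the same seed reproduces the series exactly.
#' @param record_id Identifier for the record.
#' @return A [record_series()] with a defined `event_time` and
#'   `baseline_window = c(0, baseline_duration)`.
#' @export
generate_event_record <- function(params = generator_params(), seed = 1L,
                                  record_id = "event_1") {
  p <- params
  times <- seq(0, p$duration, by = p$sample_interval)
  drift_t <- pmax(times - p$baseline_duration, 0)
  with_seed(seed, {
    n <- length(times)
    hr <- p$hr_mean + p$hr_drift * drift_t + stats::rnorm(n, 0, p$hr_sd)
    sbp <- p$sbp_mean - p$sbp_drift * drift_t + stats::rnorm(n, 0, p$sbp_sd)
    map <- p$map_mean - p$map_drift * drift_t + stats::rnorm(n, 0, p$map_sd)
    hr <- pmax(hr, 1); sbp <- pmax(sbp, 1)
    hit <- which(map <= p$map_mean - p$map_drop)
    if (!length(hit)) {
      stop("no ", p$map_drop, " mmHg MAP drop within ", p$duration,
           " min; increase `map_drift` or `duration`", call. = FALSE)
    }
    record_series(record_id, times, hr, sbp, map,
                  record_type = "event", event_time = times[hit[1L]],
                  baseline_window = c(0, p$baseline_duration))
  })
}

#' Generate a synthetic non-event (control) record
#'
#' Stationary Gaussian noise around baseline means for
#' `params$nonevent_duration` minutes, with no event annotation — a
#' hemodynamically stable segment.
#'
#' @inheritParams generate_event_record
#' @return A [record_series()] with `event_time = NA`.
#' @export
generate_nonevent_record <- function(params = generator_params(), seed = 1L,
                                     record_id = "nonevent_1") {
  p <- params
  times <- seq(0, p$nonevent_duration, by = p$sample_interval)
  with_seed(seed, {
    n <- length(times)
    hr <- pmax(p$nonevent_hr_mean + stats::rnorm(n, 0, p$hr_sd), 1)
    sbp <- pmax(p$sbp_mean + stats::rnorm(n, 0, p$sbp_sd), 1)
    map <- p$map_mean + stats::rnorm(n, 0, p$map_sd)
    record_series(record_id, times, hr, sbp, map,
                  record_type = "nonevent", event_time = NA_real_,
                  baseline_window = c(0, p$nonevent_duration))
  })
}

#' Generate a full synthetic cohort
#'
#' @param n_event,n_nonevent Numbers of event and non-event records.
#' @param params Settings from [generator_params()].
#' @param seed Integer seed; per-record seeds are derived from it.
#' @return Named list of [record_series()] objects.
#' @export
generate_cohort <- function(n_event, n_nonevent,
                            params = generator_params(), seed = 1L) {
  if (n_event + n_nonevent < 1L) {
    stop("cohort must contain at least one record", call. = FALSE)
  }
  sub_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max,
                                    n_event + n_nonevent))
  records <- c(
    lapply(seq_len(n_event), function(i) {
      generate_event_record(params, sub_seeds[i],
                            record_id = sprintf("event_%02d", i))
    }),
    lapply(seq_len(n_nonevent), function(i) {
      generate_nonevent_record(params, sub_seeds[n_event + i],
                               record_id = sprintf("nonevent_%02d", i))
    })
  )
  names(records) <- vapply(records, `[[`, "", "record_id")
  records
}

# Candidate lead times (in grid steps) for each bin, spaced two steps apart so
# single-sample pulses never merge into one episode.
fixture_leads <- function(config) {
  dt <- config$sample_interval
  m0 <- ceiling(config$t_min / dt)       # smallest on-grid On-Time lead
  mE <- ceiling(config$t_max / dt)       # smallest on-grid Early lead
  on_ms <- seq(m0, mE - 2L, by = 2L)
  on_ms <- on_ms[on_ms * dt < config$t_max & on_ms * dt >= config$t_min]
  list(m0 = m0, mE = mE, dt = dt, on_ms = on_ms)
}

#' Construct traces and records realizing exact bin counts
#'
#' Builds a cohort of annotated records and single-sample warning pulses whose
#' onsets fall in prescribed bins, so that `count_bins(build_fiducials(...))`
#' reproduces `spec` exactly. On-Time pulses sit at on-grid leads inside
#' `[t_min, t_max)`, Early pulses at leads `>= t_max`, Late pulses at leads
#' `< t_min` (running past the event when needed), and False pulses at
#' randomized positions on non-event records. Warnings are spread round-robin
#' across the non-missed event records.
#'
#' @param spec A [bin_counts()] object (the target counts).
#' @param config A [framework_config()].
#' @param seed Integer seed (randomizes False-pulse placement).
#' @return List with `traces` (named list of [warning_trace()]) and
#'   `records` (named list of [record_series()]).
#' @export
generate_fixture <- function(spec, config, seed = 1L) {
  stopifnot(inherits(spec, "bin_counts"), inherits(config, "framework_config"))
  dt <- config$sample_interval
  L <- fixture_leads(config)
  n_warners <- spec$n_event_records - spec$n_missed
  n_event_warnings <- spec$n_early + spec$n_on_time + spec$n_late
  if (n_warners == 0L && n_event_warnings > 0L) {
    stop("unachievable fixture: event-side warnings but every event record ",
         "is missed", call. = FALSE)
  }
  # every non-missed event record must carry at least one warning, or it
  # would itself be missed
  if (n_event_warnings < n_warners) {
    stop("unachievable fixture: ", n_warners, " warned event records but ",
         "only ", n_event_warnings, " event-side warnings", call. = FALSE)
  }
  if (spec$n_nonevent_records == 0L && spec$n_false > 0L) {
    stop("unachievable fixture: False warnings need non-event records",
         call. = FALSE)
  }
  # distribute the event-side warnings round-robin across the warner records
  # globally (not per bin), so every non-missed event record gets >= 1
  cats <- rep(c("E", "O", "L"),
              c(spec$n_early, spec$n_on_time, spec$n_late))
  rec_of <- if (length(cats) && n_warners > 0L)
    (seq_along(cats) - 1L) %% n_warners + 1L else integer()
  e_per <- tabulate(rec_of[cats == "E"], nbins = n_warners)
  o_per <- tabulate(rec_of[cats == "O"], nbins = n_warners)
  l_per <- tabulate(rec_of[cats == "L"], nbins = n_warners)
  if (n_warners > 0L && max(c(o_per, 0L)) > length(L$on_ms)) {
    stop("unachievable fixture: up to ", max(o_per), " On-Time warnings on ",
         "one record but only ", length(L$on_ms),
         " separated on-grid leads fit in [t_min, t_max)", call. = FALSE)
  }
  max_e <- if (length(e_per)) max(e_per) else 0L
  max_l <- if (length(l_per)) max(l_per) else 0L
  # size the grid: event at t_e, room for the largest Early lead before it
  # and the deepest Late (post-event) pulse after it
  t_e <- (L$mE + 2L * max_e + 2L) * dt
  t_end <- t_e + (max(2L * max_l - L$m0, 0L) + 4L) * dt
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  time_index <- function(t) as.integer(round(t / dt)) + 1L
  const <- function(x) rep(x, n)
  make_event <- function(id, n_e, n_o, n_l) {
    leads <- c(if (n_e > 0L) (L$mE + 2L * (seq_len(n_e) - 1L)) * dt,
               if (n_o > 0L) L$on_ms[seq_len(n_o)] * dt,
               if (n_l > 0L) (L$m0 - 2L * seq_len(n_l)) * dt)
    onsets <- t_e - leads
    state <- integer(n)
    state[time_index(onsets)] <- 1L
    list(record = record_series(id, times, const(80), const(120), const(90),
                                record_type = "event", event_time = t_e,
                                baseline_window = c(0, dt)),
         trace = warning_trace(id, times, state))
  }
  make_nonevent <- function(id, n_f) {
    slots <- seq(2L, n - 1L, by = 2L)    # interior, pairwise non-adjacent
    if (n_f > length(slots)) {
      stop("unachievable fixture: ", n_f, " False warnings on one record ",
           "but only ", length(slots), " separated slots", call. = FALSE)
    }
    state <- integer(n)
    if (n_f > 0L) state[sort(sample(slots, n_f))] <- 1L
    list(record = record_series(id, times, const(80), const(120), const(90),
                                record_type = "nonevent",
                                event_time = NA_real_,
                                baseline_window = c(0, t_end)),
         trace = warning_trace(id, times, state))
  }
  with_seed(seed, {
    f_per <- if (spec$n_nonevent_records > 0L)
      tabulate((seq_len(spec$n_false) - 1L) %% spec$n_nonevent_records + 1L,
               nbins = spec$n_nonevent_records) else integer()
    parts <- c(
      lapply(seq_len(n_warners), function(i) {
        make_event(sprintf("event_%03d", i), e_per[i], o_per[i], l_per[i])
      }),
      lapply(seq_len(spec$n_missed), function(i) {
        make_event(sprintf("event_%03d", n_warners + i), 0L, 0L, 0L)
      }),
      lapply(seq_len(spec$n_nonevent_records), function(i) {
        make_nonevent(sprintf("nonevent_%03d", i), f_per[i])
      })
    )
    records <- lapply(parts, `[[`, "record")
    traces <- lapply(parts, `[[`, "trace")
    names(records) <- names(traces) <- vapply(records, `[[`, "", "record_id")
    list(traces = traces, records = records)
  })
}
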