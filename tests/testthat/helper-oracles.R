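# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive case analysis / interval arithmetic, not by calling package
# internals, so they can arbitrate the implementation.

# Five-bin categorization by explicit case analysis, one row at a time.
oracle_categorize <- function(record_type, time_event, time_warning,
                              t_min, t_max) {
  if (record_type == "nonevent") {
    if (is.na(time_warning)) return(NA_character_)  # roster row, not a warning
    return("False")
  }
  # event record
  if (is.na(time_warning)) return("Missed")
  lead <- time_event - time_warning
  if (lead >= t_max) return("Early")
  if (lead >= t_min && lead < t_max) return("On Time")
  "Late"
}

oracle_count_bins <- function(rows, t_min, t_max) {
  cats <- vapply(seq_len(nrow(rows)), function(i) {
    c_ <- oracle_categorize(rows$record_type[i], rows$time_event_min[i],
                            rows$time_warning_min[i], t_min, t_max)
    if (is.na(c_)) "none" else c_
  }, "")
  c(n_false = sum(cats == "False"), n_early = sum(cats == "Early"),
    n_on_time = sum(cats == "On Time"), n_late = sum(cats == "Late"),
    n_missed = sum(cats == "Missed"))
}

# Latch oracle by interval merging: extract input episodes by scanning, merge
# neighbours whose onset-to-previous-offset distance is below off_delay,
# apply the trailing-gap rule, rasterize back to the grid.
oracle_latch <- function(state, times, off_delay) {
  n <- length(state)
  if (off_delay == 0 || !any(state == 1L)) return(state)
  dt <- times[2L] - times[1L]
  # scan for episodes
  eps <- list()
  i <- 1L
  while (i <= n) {
    if (state[i] == 1L) {
      j <- i
      while (j < n && state[j + 1L] == 1L) j <- j + 1L
      eps[[length(eps) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  merged <- list(eps[[1L]])
  for (k in seq_along(eps)[-1L]) {
    prev <- merged[[length(merged)]]
    gap <- times[eps[[k]][1L]] - times[prev[2L]]
    if (gap < off_delay) {
      merged[[length(merged)]] <- c(prev[1L], eps[[k]][2L])
    } else {
      merged[[length(merged) + 1L]] <- eps[[k]]
    }
  }
  last <- merged[[length(merged)]]
  if (times[n] - times[last[2L]] < off_delay) {
    merged[[length(merged)]] <- c(last[1L], n)
  }
  out <- integer(n)
  for (m in merged) out[m[1L]:m[2L]] <- 1L
  out
}

# Random valid fiducial table: a mix of event/nonevent records, multiple
# warnings per record, NA-warning roster rows for some records.
random_fiducials <- function(n_rows, t_ref = 60) {
  n_ev <- sample.int(8L, 1L)
  n_ne <- sample.int(8L, 1L)
  ev_ids <- sprintf("ev%02d", seq_len(n_ev))
  ne_ids <- sprintf("ne%02d", seq_len(n_ne))
  ev_times <- stats::setNames(stats::runif(n_ev, 30, 120), ev_ids)
  rows <- lapply(seq_len(n_rows), function(i) {
    if (stats::runif(1) < n_ev / (n_ev + n_ne)) {
      id <- sample(ev_ids, 1L)
      tw <- if (stats::runif(1) < 0.1) NA_real_ else
        ev_times[[id]] - stats::runif(1, -20, 40)   # leads from -20 to 40 min
      data.frame(record_id = id, record_type = "event",
                 time_event_min = ev_times[[id]], time_warning_min = tw,
                 stringsAsFactors = FALSE)
    } else {
      id <- sample(ne_ids, 1L)
      tw <- if (stats::runif(1) < 0.1) NA_real_ else stats::runif(1, 0, 120)
      data.frame(record_id = id, record_type = "nonevent",
                 time_event_min = NA_real_, time_warning_min = tw,
                 stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  # at most one NA-warning roster row per record, and none for records that
  # also carry real warnings (a roster row marks a warningless record)
  keep <- rep(TRUE, nrow(df))
  for (id in unique(df$record_id)) {
    idx <- which(df$record_id == id)
    na_idx <- idx[is.na(df$time_warning_min[idx])]
    if (length(na_idx) && length(na_idx) < length(idx)) {
      keep[na_idx] <- FALSE
    } else if (length(na_idx) > 1L) {
      keep[na_idx[-1L]] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

# Random binary trace on a uniform grid.
random_trace <- function(n = 60L, p_on = 0.3, dt = 1, id = "r1") {
  warning_trace(id, seq(0, by = dt, length.out = n),
                stats::rbinom(n, 1L, p_on))
}
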