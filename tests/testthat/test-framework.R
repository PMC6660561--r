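cfg <- framework_config()   # t_min 1, t_max 14, threshold 0.9, off_delay 10

fid_row <- function(type, te, tw, id = "r1") {
  as_fiducial_table(data.frame(record_id = id, record_type = type,
                               time_event_min = te, time_warning_min = tw,
                               stringsAsFactors = FALSE))
}

test_that("categorize applies the five rules with the stated boundaries", {
  # boundary: lead exactly t_max is Early; exactly t_min is On Time
  expect_equal(categorize(fid_row("event", 40, 26), cfg), "Early")    # lead 14
  expect_equal(categorize(fid_row("event", 40, 39), cfg), "On Time")  # lead 1
  expect_equal(categorize(fid_row("event", 40, 39.5), cfg), "Late")   # lead .5
  # onset after the event: negative lead still satisfies lead < t_min
  expect_equal(categorize(fid_row("event", 40, 45), cfg), "Late")     # lead -5
  expect_equal(categorize(fid_row("nonevent", NA, 12), cfg), "False")
  expect_equal(categorize(fid_row("event", 40, NA), cfg), "Missed")
  # warningless non-event roster row is not categorizable
  expect_true(is.na(categorize(fid_row("nonevent", NA, NA), cfg)))
})

test_that("categorize depends only on the lead time", {
  withr::with_seed(31, {
    for (i in 1:50) {
      te <- runif(1, 20, 100); lead <- runif(1, -20, 40)
      shift <- runif(1, -10, 50)
      a <- categorize(fid_row("event", te, te - lead), cfg)
      b <- categorize(fid_row("event", te + shift, te + shift - lead), cfg)
      expect_identical(a, b)
    }
  })
})

test_that("count_bins matches the brute-force oracle on random tables", {
  withr::with_seed(41, {
    for (i in 1:60) {
      df <- as_fiducial_table(random_fiducials(sample.int(200, 1)))
      ct <- count_bins(df, cfg)
      expect_equal(
        c(n_false = ct$n_false, n_early = ct$n_early,
          n_on_time = ct$n_on_time, n_late = ct$n_late,
          n_missed = ct$n_missed),
        oracle_count_bins(df, cfg$t_min, cfg$t_max))
      expect_equal(ct$n_event_records,
                   length(unique(df$record_id[df$record_type == "event"])))
      expect_equal(ct$n_nonevent_records,
                   length(unique(df$record_id[df$record_type == "nonevent"])))
    }
  })
})

test_that("count_bins of an empty table is all zero", {
  ct <- count_bins(fiducial_table(), cfg)
  expect_equal(ct$total_warnings, 0L)
  expect_equal(ct$n_event_records, 0L)
})

# The printed case study: both strategies' tallies over 16 event and
# 12 non-event records.
responsive_counts <- bin_counts(30, 18, 12, 2, 1, 16, 12)
stay_on_counts <- bin_counts(8, 6, 10, 1, 1, 16, 12)

test_that("warning proportions reproduce the case-study columns", {
  wp <- warning_proportions(responsive_counts)
  expect_equal(round(wp, 2),
               c(False = 0.48, Early = 0.29, `On Time` = 0.19,
                 Late = 0.03, Missed = 0.02))
  wp2 <- warning_proportions(stay_on_counts)
  expect_equal(round(wp2, 2),
               c(False = 0.32, Early = 0.24, `On Time` = 0.40,
                 Late = 0.04, Missed = 0.04))
  # ideal system
  ideal <- warning_proportions(bin_counts(0, 0, 5, 0, 0, 5, 1))
  expect_equal(unname(ideal), c(0, 0, 1, 0, 0))
  expect_error(warning_proportions(bin_counts(0, 0, 0, 0, 1, 2, 1)),
               "zero warnings")
})

test_that("the four warning-bin proportions sum to exactly 1 pre-rounding", {
  withr::with_seed(51, {
    for (i in 1:50) {
      df <- as_fiducial_table(random_fiducials(sample.int(150, 1) + 5))
      ct <- count_bins(df, cfg)
      if (ct$total_warnings == 0L) next
      wp <- warning_proportions(ct)
      expect_equal(sum(wp[c("False", "Early", "On Time", "Late")]), 1,
                   tolerance = 1e-12)
      expect_gte(sum(wp), 1)
    }
  })
})

test_that("warnings per record reproduce the case-study columns", {
  wr <- warnings_per_record(responsive_counts)
  expect_equal(round(wr, 2),
               c(False = 2.5, Early = 1.12, `On Time` = 0.75,
                 Late = 0.12, Missed = 0.06),
               ignore_attr = TRUE)
  wr2 <- warnings_per_record(stay_on_counts)
  expect_equal(round(wr2, 2),
               c(False = 0.67, Early = 0.38, `On Time` = 0.62,
                 Late = 0.06, Missed = 0.06),
               ignore_attr = TRUE)
  # event-side sum is the warnings-to-records burden ratio
  expect_equal(round(sum(wr[-1]), 2), 2.06)
  expect_equal(round(sum(wr2[-1]), 2), 1.12)
  # one timely warning per event record
  one <- warnings_per_record(bin_counts(0, 0, 7, 0, 0, 7, 3))
  expect_equal(unname(one["On Time"]), 1)
})

test_that("warnings_per_record handles zero denominators as specified", {
  expect_error(warnings_per_record(bin_counts(3, 0, 0, 0, 0, 1, 0)),
               "zero record denominator")
  ok <- warnings_per_record(bin_counts(0, 1, 1, 0, 0, 2, 0))
  expect_equal(unname(ok["False"]), 0)
  expect_equal(attr(ok, "undefined_bins"), "False")
})

make_trace_record <- function(id, type, event_time, on_times, t_end = 120) {
  times <- 0:t_end
  state <- integer(length(times))
  state[times %in% on_times] <- 1L
  list(record = record_series(id, times, rep(80, length(times)),
                              rep(120, length(times)),
                              record_type = type,
                              event_time = if (type == "event") event_time
                                           else NA_real_),
       trace = warning_trace(id, times, state))
}

test_that("traditional metrics reproduce the case-study percentages", {
  # 16 event records, 14 with an active sample inside the window;
  # 12 non-event records, 5 with any active sample
  parts <- c(
    lapply(1:14, function(i) {
      make_trace_record(sprintf("e%02d", i), "event", 60, on_times = 55)
    }),
    # warned, but outside the window (lead 20 >= t_max)
    lapply(15:16, function(i) {
      make_trace_record(sprintf("e%02d", i), "event", 60, on_times = 40)
    }),
    lapply(1:5, function(i) {
      make_trace_record(sprintf("n%02d", i), "nonevent", NA, on_times = 30)
    }),
    lapply(6:12, function(i) {
      make_trace_record(sprintf("n%02d", i), "nonevent", NA,
                        on_times = integer())
    })
  )
  records <- lapply(parts, `[[`, "record")
  traces <- lapply(parts, `[[`, "trace")
  names(records) <- names(traces) <-
    vapply(records, `[[`, "", "record_id")
  m <- traditional_metrics(traces, records, cfg)
  expect_equal(m$n_true_positive_records, 14L)
  expect_equal(m$n_false_positive_records, 5L)
  expect_equal(round(m$ppv, 1), 73.7)          # 14/19
  expect_equal(round(m$sensitivity, 1), 87.5)  # 14/16
  # 5/12 computes to 41.7, not the printed 42.7 (known discrepancy)
  expect_equal(round(m$false_positive_rate, 1), 41.7)
})

test_that("traditional metrics use the same half-open window as the bins", {
  # active only at lead exactly t_max: Early for the bins, not in-window
  p1 <- make_trace_record("e1", "event", 60, on_times = 60 - cfg$t_max)
  # active at lead exactly t_min: in-window
  p2 <- make_trace_record("e2", "event", 60, on_times = 60 - cfg$t_min)
  records <- list(e1 = p1$record, e2 = p2$record)
  traces <- list(e1 = p1$trace, e2 = p2$trace)
  m <- traditional_metrics(traces, records, cfg)
  expect_equal(m$n_true_positive_records, 1L)
})

test_that("no warnings anywhere gives zero TP/FP and undefined PPV", {
  p1 <- make_trace_record("e1", "event", 60, integer())
  p2 <- make_trace_record("n1", "nonevent", NA, integer())
  m <- traditional_metrics(list(e1 = p1$trace, n1 = p2$trace),
                           list(e1 = p1$record, n1 = p2$record), cfg)
  expect_equal(m$n_true_positive_records, 0L)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$false_positive_rate, 0)
  expect_true(is.na(m$ppv))
})

test_that("build_fiducials expands episodes and adds roster rows", {
  ev <- record_series("e1", 0:120, rep(80, 121), rep(120, 121),
                      record_type = "event", event_time = 40)
  ev2 <- record_series("e2", 0:120, rep(80, 121), rep(120, 121),
                       record_type = "event", event_time = 40)
  ne <- record_series("n1", 0:120, rep(80, 121), rep(120, 121),
                      record_type = "nonevent")
  eps <- data.frame(record_id = c("e1", "e1", "n1"),
                    onset = c(20, 35, 12), offset = c(21, 36, 12))
  fid <- build_fiducials(eps, list(e1 = ev, e2 = ev2, n1 = ne),
                         length_ratio_warn = Inf)
  expect_equal(nrow(fid), 4L)   # 3 episodes + 1 warningless record
  e1 <- fid[fid$record_id == "e1", ]
  expect_equal(sort(e1$time_warning_min), c(20, 35))
  expect_equal(unique(e1$time_event_min), 40)
  expect_true(is.na(fid$time_warning_min[fid$record_id == "e2"]))
  expect_equal(fid$time_warning_min[fid$record_id == "n1"], 12)
  expect_true(is.na(fid$time_event_min[fid$record_id == "n1"]))
  # unknown record id
  bad <- data.frame(record_id = "zz", onset = 1, offset = 1)
  expect_error(build_fiducials(bad, list(e1 = ev)), "unknown record")
})

test_that("build_fiducials warns on strong record-length disparity", {
  long <- record_series("a", 0:120, rep(80, 121), rep(120, 121))
  short <- record_series("b", 0:10, rep(80, 11), rep(120, 11))
  expect_warning(
    build_fiducials(data.frame(record_id = character(), onset = numeric()),
                    list(a = long, b = short)),
    "lengths differ")
})

test_that("TP count is at least the number of records with an On-Time onset", {
  withr::with_seed(61, {
    for (i in 1:20) {
      n_missed <- sample(0:2, 1)
      warners <- 6L - n_missed
      fx <- generate_fixture(
        bin_counts(sample(0:5, 1), sample(0:4, 1),
                   sample(warners:(warners + 3L), 1),
                   sample(0:3, 1), n_missed,
                   n_event_records = 6, n_nonevent_records = 4),
        cfg, seed = i)
      fid <- build_fiducials(do.call(rbind,
                                     lapply(fx$traces, extract_episodes)),
                             fx$records, length_ratio_warn = Inf)
      cats <- categorize(fid, cfg)
      n_ontime_records <-
        length(unique(fid$record_id[!is.na(cats) & cats == "On Time"]))
      m <- traditional_metrics(fx$traces, fx$records, cfg)
      expect_gte(m$n_true_positive_records, n_ontime_records)
    }
  })
})
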