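test_that("zero-noise event generator hits the closed-form drift crossing", {
  p <- generator_params(hr_sd = 0, sbp_sd = 0, map_sd = 0,
                        map_mean = 90, map_drift = 1, baseline_duration = 30)
  r <- generate_event_record(p, seed = 1)
  expect_equal(r$event_time, 30 + 30 / 1)   # baseline + drop/drift
  expect_equal(r$baseline_window, c(0, 30))
  # doubling the drift halves the post-baseline time to event
  p2 <- generator_params(hr_sd = 0, sbp_sd = 0, map_sd = 0, map_drift = 2)
  r2 <- generate_event_record(p2, seed = 1)
  expect_equal(r2$event_time - 30, (r$event_time - 30) / 2)
  # zero noise, no drift reaching the drop -> explicit no-event error
  p3 <- generator_params(map_sd = 0, map_drift = 0.1, duration = 60)
  expect_error(generate_event_record(p3, seed = 1), "MAP drop")
})

test_that("generators are deterministic in the seed", {
  r1 <- generate_event_record(seed = 42)
  r2 <- generate_event_record(seed = 42)
  expect_equal(r1, r2)
  n1 <- generate_nonevent_record(seed = 42)
  n2 <- generate_nonevent_record(seed = 42)
  expect_equal(n1, n2)
  expect_false(isTRUE(all.equal(generate_nonevent_record(seed = 1)$hr,
                                generate_nonevent_record(seed = 2)$hr)))
  # and do not disturb the global RNG stream
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(generate_event_record(seed = 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("non-event records are stationary with undefined event time", {
  r <- generate_nonevent_record(seed = 9)
  expect_true(is.na(r$event_time))
  expect_equal(r$record_type, "nonevent")
  expect_equal(max(r$times), 120)          # 2 h default
  p0 <- generator_params(hr_sd = 0, sbp_sd = 0, map_sd = 0)
  r0 <- generate_nonevent_record(p0, seed = 1)
  expect_equal(unique(r0$hr), p0$nonevent_hr_mean)
  expect_equal(unique(r0$sbp), p0$sbp_mean)
})

test_that("generate_cohort builds the requested composition", {
  recs <- generate_cohort(3, 2, seed = 4)
  expect_length(recs, 5L)
  types <- vapply(recs, `[[`, "", "record_type")
  expect_equal(sum(types == "event"), 3L)
  expect_equal(sum(types == "nonevent"), 2L)
  expect_error(generate_cohort(0, 0), "at least one record")
})

cfg <- framework_config()

fixture_counts <- function(fx, config = cfg) {
  ep <- do.call(rbind, lapply(fx$traces, extract_episodes))
  count_bins(build_fiducials(ep, fx$records, length_ratio_warn = Inf),
             config)
}

test_that("generate_fixture reproduces the case-study counts exactly", {
  spec <- bin_counts(30, 18, 12, 2, 1, 16, 12)
  got <- fixture_counts(generate_fixture(spec, cfg, seed = 2))
  expect_equal(got, spec)
  spec2 <- bin_counts(0, 0, 1, 0, 0, 1, 0)
  expect_equal(fixture_counts(generate_fixture(spec2, cfg, seed = 2)), spec2)
})

test_that("fixture round-trip holds for randomized achievable specs", {
  withr::with_seed(8, {
    for (i in 1:40) {
      n_ev <- sample(1:10, 1); n_ne <- sample(0:8, 1)
      n_missed <- sample(0:n_ev, 1)
      warners <- n_ev - n_missed
      spec <- bin_counts(
        n_false = if (n_ne > 0) sample(0:(3 * n_ne), 1) else 0L,
        n_early = if (warners > 0) sample(0:(2 * warners), 1) else 0L,
        # at least one warning per non-missed event record
        n_on_time = if (warners > 0) sample(warners:(4 * warners), 1) else 0L,
        n_late = if (warners > 0) sample(0:warners, 1) else 0L,
        n_missed = n_missed,
        n_event_records = n_ev, n_nonevent_records = n_ne)
      fx <- generate_fixture(spec, cfg, seed = i)
      expect_equal(fixture_counts(fx), spec)
    }
  })
})

test_that("unachievable fixtures are rejected", {
  expect_error(
    generate_fixture(bin_counts(5, 0, 0, 0, 0, 0, 0), cfg, seed = 1),
    "non-event records")
  # a non-missed event record with no warnings would itself be missed
  expect_error(
    generate_fixture(bin_counts(0, 1, 1, 0, 0, 3, 0), cfg, seed = 1),
    "only 2 event-side warnings")
  expect_error(
    generate_fixture(bin_counts(0, 1, 0, 0, 2, 2, 1), cfg, seed = 1),
    "missed")
  # more On-Time warnings on one record than separated grid leads fit
  tight <- framework_config(t_min = 1, t_max = 3)
  expect_error(
    generate_fixture(bin_counts(0, 0, 9, 0, 0, 1, 0), tight, seed = 1),
    "On-Time")
})

test_that("on generated cohorts STAY-ON never raises more warnings", {
  withr::with_seed(17, {
    for (i in 1:5) {
      recs <- generate_cohort(4, 3, seed = sample.int(1e6, 1))
      res <- characterize(recs, cfg)
      expect_lte(res$stay_on$counts$total_warnings,
                 res$responsive$counts$total_warnings)
    }
  })
})
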