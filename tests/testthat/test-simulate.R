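test_that("degenerate Bernoulli modes produce constant traces", {
  all_on <- sample_day_traces(list(single_mode(1)), n_days = 5, seed = 1)
  expect_true(all(trace_matrix(all_on$traces) == 1))
  expect_equal(nrow(all_on$traces), 5)

  all_off <- sample_day_traces(list(single_mode(0)), n_days = 5, seed = 1)
  expect_true(all(trace_matrix(all_off$traces) == 0))
})

test_that("mode sampling validates its inputs and names the offender", {
  expect_error(sample_day_traces(list(), 5, seed = 1), "at least one mode")
  bad <- list(single_mode(0.5, n_bins = 48, weight = 0.5),
              mode_spec("odd-bins", rep(0.5, 24), 0.5))
  expect_error(sample_day_traces(bad, 5, seed = 1), "odd-bins")
  unnorm <- list(single_mode(0.5, weight = 0.4), single_mode(0.5, name = "b", weight = 0.4))
  expect_error(sample_day_traces(unnorm, 5, seed = 1), "sum to 1")
  expect_error(mode_spec("m", c(0.5, 1.2), 1), "\\[0, 1\\]")
})

test_that("per-bin empirical frequencies converge to the mode probabilities", {
  modes <- sleep_mode_presets(weights = c(0.5, 0.5))
  sim <- sample_day_traces(modes, n_days = 200, seed = 1)
  m <- trace_matrix(sim$traces)
  for (i in 1:2) {
    rows <- sim$truth$mode_labels$mode == modes[[i]]$name
    emp <- colMeans(m[rows, , drop = FALSE])
    expect_lt(max(abs(emp - modes[[i]]$bin_probabilities)), 0.08)
  }
})

test_that("identical seeds give identical traces and events", {
  modes <- sleep_mode_presets()
  a <- sample_day_traces(modes, 20, seed = 99)
  b <- sample_day_traces(modes, 20, seed = 99)
  expect_identical(a$traces, b$traces)
  expect_identical(traces_to_events(a$traces, fill_fraction = 0.6, seed = 3),
                   traces_to_events(b$traces, fill_fraction = 0.6, seed = 3))
})

test_that("trace-to-event expansion matches the stated on/off times", {
  m <- matrix(0, 1, 48, dimnames = list(NULL, bin_labels(30)))
  m[1, "13:30"] <- 1
  tr <- new_day_traces(as.Date("2024-06-01"), m)
  ev <- traces_to_events(tr, fill_fraction = 1, seed = 1)
  expect_equal(nrow(ev), 2)
  expect_equal(format(ev$timestamp_utc, "%H:%M"), c("13:30", "14:00"))
  expect_equal(ev$event, c("on", "off"))

  empty <- new_day_traces(as.Date("2024-06-01"), matrix(0, 1, 48))
  expect_equal(nrow(traces_to_events(empty, seed = 1)), 0)
})

test_that("trace-to-event expansion warns when fill cannot satisfy tmin", {
  tr <- new_day_traces(as.Date("2024-06-01"), matrix(1, 1, 48))
  expect_warning(traces_to_events(tr, fill_fraction = 0.1, seed = 1, tmin = 5),
                 "round-trip")
})

test_that("events round-trip through binning back to the generated traces", {
  sim <- sample_day_traces(sleep_mode_presets(), n_days = 100, seed = 7)
  for (ff in c(1, 0.4)) {
    ev <- traces_to_events(sim$traces, fill_fraction = ff, seed = 11)
    rec <- bin_day_traces(ev, dates = sim$traces$date, bin_width = 30, tmin = 5)
    expect_identical(trace_matrix(rec), trace_matrix(sim$traces))
  }
})

test_that("daily count simulation honors the stated Poisson means", {
  sc <- count_scenario(1000, baseline_rate = 4, seed = 7)
  sim <- simulate_daily_counts(sc)
  expect_lt(abs(mean(sim$counts$count) - 4), 0.2)
  expect_equal(sim$truth$expected_rates$rate, rep(4, 1000))

  sc2 <- count_scenario(30, 4, abrupt_start_day = 20, abrupt_log_effect = log(2), seed = 1)
  r2 <- simulate_daily_counts(sc2)$truth$expected_rates$rate
  expect_equal(r2[19], 4)
  expect_equal(r2[20], 8)

  sc3 <- count_scenario(30, 4, outlier_days = c("15" = 5), seed = 1)
  r3 <- simulate_daily_counts(sc3)$truth$expected_rates$rate
  expect_equal(r3[15], 20)
  expect_equal(r3[14], 4)

  # variance also matches the Poisson mean at large n
  expect_lt(abs(stats::var(sim$counts$count) - 4), 0.6)
})

test_that("count scenarios reject invalid parameters", {
  expect_error(count_scenario(10, baseline_rate = 0), "baseline_rate")
  expect_error(count_scenario(10, 4, abrupt_start_day = 11), "1..n_days")
  expect_error(count_scenario(10, 4, outlier_days = c("3" = -1)), "> 0")
})

test_that("counts round-trip through synthesized visit events", {
  sc <- count_scenario(40, baseline_rate = 4, seed = 3)
  sim <- simulate_daily_counts(sc)
  ev <- counts_to_events(sim$counts)
  rec <- daily_visit_counts(ev, visit_gap = 5)
  joined <- dplyr::left_join(sim$counts, rec, by = "date", suffix = c("", ".rec"))
  nonzero <- joined$count > 0
  expect_equal(joined$count[nonzero], joined$count.rec[nonzero])
})

test_that("transmission schedule tags preserve payloads and ground truth", {
  sim <- sample_day_traces(sleep_mode_presets(), n_days = 50, seed = 5)
  ev <- traces_to_events(sim$traces, seed = 5)
  days <- sim$traces$date
  res <- inject_transmission_schedule(ev, missed_days = days[c(3, 10, 20, 30)],
                                      severe_days = days[c(10, 20, 30)], seed = 2)
  expect_identical(res$events$timestamp_utc, ev$timestamp_utc)
  expect_identical(res$truth$severe_failure_days, days[c(10, 20, 30)])
  expect_error(
    inject_transmission_schedule(ev, missed_days = days[1], severe_days = days[2]),
    "subset"
  )
})

test_that("ground truth writes as a JSON sidecar", {
  sim <- sample_day_traces(sleep_mode_presets(), n_days = 5, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(length(parsed$mode_labels), 5)
})
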