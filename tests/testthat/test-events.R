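test_that("event files round-trip and come back sorted", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp_utc,sensor_id,sensor_type,event,burst_id", path)
  expect_equal(nrow(read_events(path)), 0)

  ev <- make_events(c("2024-01-01 10:00:00", "2024-01-01 08:00:00"),
                    c("off", "on"))
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$timestamp_utc, sort(ev$timestamp_utc))
  expect_equal(back$event, c("on", "off"))

  sim <- sample_day_traces(sleep_mode_presets(), n_days = 10, seed = 1)
  ev2 <- traces_to_events(sim$traces, seed = 1)
  write_events(ev2, path)
  expect_equal(as.data.frame(read_events(path)), as.data.frame(ev2))
})

test_that("malformed event files fail loudly with line numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp_utc,sensor_id,sensor_type,event,burst_id",
               "2024-01-01T08:00:00Z,x,bed,on,",
               "not-a-time,x,bed,off,"), path)
  expect_error(read_events(path), "line 3")

  writeLines(c("timestamp_utc,sensor_id,sensor_type,event,burst_id",
               "2024-01-01T08:00:00Z,x,thermostat,on,"), path)
  expect_error(read_events(path), "thermostat")

  writeLines("time,id", path)
  expect_error(read_events(path), "header")
})

test_that("sessionization merges short gaps and drops short rests", {
  ev <- make_events(c("2024-01-01 22:00:00", "2024-01-01 22:05:00",
                      "2024-01-01 22:10:00", "2024-01-02 06:30:00"),
                    c("on", "off", "on", "off"))
  out <- sessionize(ev, gap_merge = 15, min_rest_duration = 10)
  expect_equal(nrow(out), 1)
  expect_equal(format(out$start, "%H:%M"), "22:00")
  expect_equal(format(out$end, "%H:%M"), "06:30")

  short <- make_events(c("2024-01-01 10:00:00", "2024-01-01 10:03:00"),
                       c("on", "off"))
  expect_equal(nrow(sessionize(short, min_rest_duration = 10)), 0)
})

test_that("sessionization is robust to malformed on/off sequences", {
  # repeated on extends; orphan off dropped with a warning; dangling on closes
  ev <- make_events(c("2024-01-01 08:00:00", "2024-01-01 09:00:00",
                      "2024-01-01 09:30:00", "2024-01-01 10:00:00",
                      "2024-01-01 11:00:00", "2024-01-01 12:00:00"),
                    c("off", "on", "on", "off", "on", "on"))
  expect_warning(out <- sessionize(ev, gap_merge = 5), "orphan")
  expect_equal(nrow(out), 2)
  expect_equal(format(out$start, "%H:%M"), c("09:00", "11:00"))
  expect_equal(format(out$end, "%H:%M"), c("10:00", "12:00"))
})

test_that("random on/off streams yield disjoint ordered intervals above the floor", {
  withr::with_seed(21, {
    for (i in 1:50) {
      n <- sample(4:30, 1)
      times <- as.POSIXct("2024-01-01", tz = "UTC") + sort(runif(n, 0, 3 * 86400))
      ev <- make_events(times, sample(c("on", "off"), n, replace = TRUE))
      out <- suppressWarnings(sessionize(ev, gap_merge = 15, min_rest_duration = 10))
      if (nrow(out) > 1) {
        expect_true(all(diff(as.numeric(out$start)) > 0))
        expect_true(all(as.numeric(out$start[-1]) - as.numeric(out$end[-nrow(out)]) >= 15 * 60))
      }
      expect_true(all(as.numeric(out$end) - as.numeric(out$start) >= 10 * 60))
    }
  })
})

test_that("rest ends are confirmed by nearby activity from other sensors", {
  rests <- tibble::tibble(
    start = as.POSIXct("2024-01-01 22:00:00", tz = "UTC"),
    end = as.POSIXct("2024-01-02 06:30:00", tz = "UTC"),
    confirmed_end = FALSE
  )
  pir <- make_events("2024-01-02 06:32:00", "detect", "pir-1", "pir")
  expect_true(confirm_rest_end(rests, pir, confirm_window = 10)$confirmed_end)
  far <- make_events("2024-01-02 07:30:00", "detect", "pir-1", "pir")
  expect_false(confirm_rest_end(rests, far, confirm_window = 10)$confirmed_end)
  none <- make_events(character(), character(), "pir-1", "pir")
  expect_false(confirm_rest_end(rests, none, confirm_window = 10)$confirmed_end)
})

test_that("simulated rests with injected motion are all confirmed", {
  sim <- sample_day_traces(sleep_mode_presets(), n_days = 20, seed = 13)
  ev <- traces_to_events(sim$traces, seed = 13)
  rests <- sessionize(ev, gap_merge = 15, min_rest_duration = 10)
  motion <- make_events(rests$end + 120, "detect", "pir-1", "pir")
  out <- confirm_rest_end(rests, motion, confirm_window = 10)
  expect_true(all(out$confirmed_end))
})

test_that("visit counting clusters detections and reports zero days", {
  ev <- make_events(c("2024-01-01 08:00:00", "2024-01-01 08:02:00",
                      "2024-01-01 08:30:00"),
                    "detect", "toilet-1", "toilet")
  out <- daily_visit_counts(ev, visit_gap = 5)
  expect_equal(out$count, 2L)

  span <- make_events(c("2024-01-01 08:00:00", "2024-01-03 09:00:00"),
                      "detect", "toilet-1", "toilet")
  out2 <- daily_visit_counts(span, visit_gap = 5)
  expect_equal(out2$count, c(1L, 0L, 1L))
  expect_error(daily_visit_counts(make_events("2024-01-01 08:00:00", "on")),
               "detect")
})

test_that("night visits are counted inside the local night window", {
  ev <- make_events(c("2024-01-01 23:30:00", "2024-01-02 02:00:00",
                      "2024-01-02 10:00:00"),
                    "detect", "toilet-1", "toilet")
  out <- daily_visit_counts(ev, visit_gap = 5, timezone = "Europe/Rome")
  # 23:30 UTC = 00:30 local on Jan 2 -> night; 02:00 UTC = 03:00 local -> night
  expect_equal(out$date[1], as.Date("2024-01-02"))
  expect_equal(out$count[1], 3L)
  expect_equal(out$night_count[1], 2L)
})

test_that("binning marks bins by accumulated active time against tmin", {
  iv <- tibble::tibble(start = as.POSIXct("2024-06-01 13:40:00", tz = "UTC"),
                       end = as.POSIXct("2024-06-01 14:10:00", tz = "UTC"))
  tr <- bin_day_trace(iv, as.Date("2024-06-01"), bin_width = 30, tmin = 5)
  m <- trace_matrix(tr)
  expect_equal(unname(m[1, c("13:30", "14:00")]), c(1, 1))
  expect_equal(sum(m), 2)

  iv2 <- tibble::tibble(start = as.POSIXct("2024-06-01 13:58:00", tz = "UTC"),
                        end = as.POSIXct("2024-06-01 14:01:00", tz = "UTC"))
  expect_equal(sum(trace_matrix(bin_day_trace(iv2, as.Date("2024-06-01")))), 0)

  expect_error(bin_day_trace(iv, as.Date("2024-06-01"), bin_width = 30, tmin = 31),
               "tmin")
})

test_that("binning is invariant to event order and interval splitting", {
  iv <- tibble::tibble(
    start = as.POSIXct(c("2024-06-01 01:10:00", "2024-06-01 22:00:00"), tz = "UTC"),
    end = as.POSIXct(c("2024-06-01 03:20:00", "2024-06-01 23:30:00"), tz = "UTC")
  )
  base <- trace_matrix(bin_day_trace(iv, as.Date("2024-06-01")))
  split <- tibble::tibble(
    start = as.POSIXct(c("2024-06-01 22:00:00", "2024-06-01 01:10:00",
                         "2024-06-01 02:00:00"), tz = "UTC"),
    end = as.POSIXct(c("2024-06-01 23:30:00", "2024-06-01 02:00:00",
                       "2024-06-01 03:20:00"), tz = "UTC")
  )
  expect_identical(trace_matrix(bin_day_trace(split, as.Date("2024-06-01"))), base)
})

test_that("daylight-saving days keep their true bins under canonical labels", {
  # Europe/Rome spring forward: 2024-03-31, 02:00 -> 03:00 local
  iv <- tibble::tibble(
    start = as.POSIXct("2024-03-31 00:30:00", tz = "UTC"), # 01:30 CET local
    end = as.POSIXct("2024-03-31 01:30:00", tz = "UTC")    # 03:30 CEST local
  )
  tr <- bin_day_trace(iv, as.Date("2024-03-31"), timezone = "Europe/Rome")
  m <- trace_matrix(tr)
  expect_true(all(is.na(m[1, c("02:00", "02:30")])))
  expect_equal(unname(m[1, c("01:30", "03:00")]), c(1, 1))

  # fall back: 2024-10-27, 03:00 -> 02:00 local; repeated labels collapse by OR
  iv2 <- tibble::tibble(
    start = as.POSIXct("2024-10-27 00:40:00", tz = "UTC"), # 02:40 CEST (first pass)
    end = as.POSIXct("2024-10-27 00:50:00", tz = "UTC")
  )
  tr2 <- bin_day_trace(iv2, as.Date("2024-10-27"), timezone = "Europe/Rome")
  m2 <- trace_matrix(tr2)
  expect_equal(unname(m2[1, "02:30"]), 1)
  expect_false(anyNA(m2))
})

test_that("transmission quality reproduces report arithmetic", {
  q <- transmission_quality(8970, 8231, 17)
  expect_equal(q$pct_ideal, 91.7)
  expect_equal(q$pct_severe, 0.19)
  expect_equal(transmission_quality(10, 10, 0)$pct_ideal, 100.0)
  expect_equal(transmission_quality(10, 10, 0)$pct_severe, 0.00)
  expect_equal(transmission_quality(4, 1, 1)$pct_ideal, 25.0)
  expect_equal(transmission_quality(4, 1, 1)$pct_severe, 25.00)
  expect_error(transmission_quality(0, 0, 0), "positive")
})

test_that("burst-tagged streams recover injected failure days exactly", {
  sim <- sample_day_traces(sleep_mode_presets(), n_days = 50, seed = 8)
  ev <- traces_to_events(sim$traces, seed = 8)
  days <- sim$traces$date
  res <- inject_transmission_schedule(ev, missed_days = days[c(5, 17, 33, 41)],
                                      severe_days = days[c(17, 33, 41)], seed = 4)
  q <- summarize_transmission(res$events)
  expect_equal(q$n_severe_days, 3L)
  expect_equal(q$n_total_days - q$n_ideal_days, 4L)

  clean <- inject_transmission_schedule(ev, seed = 1)
  qc <- summarize_transmission(clean$events)
  expect_equal(qc$pct_ideal, 100.0)
  expect_equal(qc$n_severe_days, 0L)
})
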