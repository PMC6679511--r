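SENSOR_TYPES <- c("bed", "chair", "toilet", "pir", "contact")
STATE_EVENTS <- c("on", "off")

valid_event_for_type <- function(sensor_type, event) {
  ifelse(sensor_type %in% c("bed", "chair", "contact"),
         event %in% STATE_EVENTS,
         event == "detect")
}

#' Read a sensor event log
#'
#' Reads the event CSV dialect: UTF-8, comma-separated, header
#' `timestamp_utc,sensor_id,sensor_type,event,burst_id`, timestamps in ISO
#' 8601 UTC with a `Z` suffix, `burst_id` possibly empty. Events are
#' returned sorted by timestamp. Unknown sensor types and unparsable
#' timestamps are hard errors naming the offending line.
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `timestamp_utc` (POSIXct, UTC), `sensor_id`,
#'   `sensor_type`, `event`, `burst_id`.
#' @seealso [write_events()]
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort(sprintf("event file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  expected <- c("timestamp_utc", "sensor_id", "sensor_type", "event", "burst_id")
  if (!identical(names(raw), expected)) {
    abort(sprintf("bad header: expected %s", paste(expected, collapse = ",")))
  }
  if (nrow(raw) == 0) {
    return(tibble(timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                  sensor_id = character(), sensor_type = character(),
                  event = character(), burst_id = character()))
  }
  ts <- as.POSIXct(raw$timestamp_utc, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0) {
    abort(sprintf("unparsable timestamp at line %s of %s",
                  paste(bad_ts + 1L, collapse = ", "), path))
  }
  bad_type <- which(!raw$sensor_type %in% SENSOR_TYPES)
  if (length(bad_type) > 0) {
    abort(sprintf("unknown sensor_type '%s' at line %d of %s",
                  raw$sensor_type[bad_type[1]], bad_type[1] + 1L, path))
  }
  bad_ev <- which(!valid_event_for_type(raw$sensor_type, raw$event))
  if (length(bad_ev) > 0) {
    abort(sprintf("invalid event '%s' for sensor_type '%s' at line %d of %s",
                  raw$event[bad_ev[1]], raw$sensor_type[bad_ev[1]],
                  bad_ev[1] + 1L, path))
  }
  out <- tibble(
    timestamp_utc = ts,
    sensor_id = raw$sensor_id,
    sensor_type = raw$sensor_type,
    event = raw$event,
    burst_id = ifelse(raw$burst_id == "", NA_character_, raw$burst_id)
  )
  arrange(out, .data$timestamp_utc)
}

#' Write a sensor event log
#'
#' Writes the exact CSV dialect read by [read_events()]; output is
#' byte-deterministic for identical input.
#'
#' @param events Sensor-event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- tibble(
    timestamp_utc = format(events$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    sensor_id = events$sensor_id,
    sensor_type = events$sensor_type,
    event = events$event,
    burst_id = ifelse(is.na(events$burst_id), "", events$burst_id)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Merge raw on/off events into rest intervals
#'
#' Pairs `on`/`off` events from a single occupancy sensor into raw presence
#' intervals, merges consecutive intervals separated by gaps shorter than
#' `gap_merge` minutes, and discards merged intervals shorter than
#' `min_rest_duration` minutes -- filtering out short bed presences
#' unrelated to actual rest. Malformed sequences are handled robustly:
#' a repeated `on` extends the open interval, an orphan `off` is dropped
#' with a warning, and a dangling `on` at end of stream closes the interval
#' at the last observed event time, flagged as unconfirmed.
#'
#' @param events Events from one bed or chair sensor (`on`/`off`).
#' @param gap_merge Gap-merging threshold in minutes (default 15).
#' @param min_rest_duration Minimum retained duration in minutes (default 10).
#' @return Tibble with columns `start`, `end` (POSIXct, UTC) and
#'   `confirmed_end` (logical; `FALSE` until [confirm_rest_end()] is
#'   applied, and for dangling intervals).
#' @export
sessionize <- function(events, gap_merge = 15, min_rest_duration = 10) {
  ev <- filter(events, .data$event %in% STATE_EVENTS)
  if (length(unique(ev$sensor_id)) > 1) {
    abort("`sessionize()` expects events from a single sensor.")
  }
  empty <- tibble(start = as.POSIXct(character(), tz = "UTC"),
                  end = as.POSIXct(character(), tz = "UTC"),
                  confirmed_end = logical())
  if (nrow(ev) == 0) return(empty)
  ev <- arrange(ev, .data$timestamp_utc)
  starts <- c(); ends <- c(); closed <- logical()
  open <- NA_real_
  n_orphan <- 0L
  for (i in seq_len(nrow(ev))) {
    t <- as.numeric(ev$timestamp_utc[i])
    if (ev$event[i] == "on") {
      if (is.na(open)) open <- t # repeated "on" just extends the open interval
    } else {
      if (is.na(open)) {
        n_orphan <- n_orphan + 1L
      } else {
        starts <- c(starts, open); ends <- c(ends, t); closed <- c(closed, TRUE)
        open <- NA_real_
      }
    }
  }
  if (!is.na(open)) {
    last_t <- as.numeric(ev$timestamp_utc[nrow(ev)])
    if (last_t > open) {
      starts <- c(starts, open); ends <- c(ends, last_t); closed <- c(closed, FALSE)
    }
  }
  if (n_orphan > 0) {
    warn(sprintf("dropped %d orphan 'off' event(s) without a matching 'on'.", n_orphan))
  }
  if (length(starts) == 0) return(empty)
  # merge gaps shorter than gap_merge minutes
  m_start <- starts[1]; m_end <- ends[1]; m_closed <- closed[1]
  out_s <- c(); out_e <- c(); out_c <- logical()
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] - m_end < gap_merge * 60) {
        m_end <- max(m_end, ends[i]); m_closed <- closed[i]
      } else {
        out_s <- c(out_s, m_start); out_e <- c(out_e, m_end); out_c <- c(out_c, m_closed)
        m_start <- starts[i]; m_end <- ends[i]; m_closed <- closed[i]
      }
    }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end); out_c <- c(out_c, m_closed)
  keep <- (out_e - out_s) >= min_rest_duration * 60
  out <- tibble(
    start = lubridate::as_datetime(out_s[keep], tz = "UTC"),
    end = lubridate::as_datetime(out_e[keep], tz = "UTC"),
    confirmed_end = rep(FALSE, sum(keep))
  )
  attr(out, "closed_by_off") <- out_c[keep]
  out
}

#' Confirm rest-interval ends by data fusion with other sensors
#'
#' A rest end is confirmed when any event from another sensor (PIR motion,
#' magnetic contact, ...) occurs within `confirm_window` minutes after the
#' interval end -- evidence that the person actually got up.
#'
#' @param intervals Rest intervals from [sessionize()].
#' @param other_events Events from sensors other than the rest sensor.
#' @param confirm_window Window after the interval end, in minutes.
#' @return `intervals` with `confirmed_end` updated.
#' @export
confirm_rest_end <- function(intervals, other_events, confirm_window = 10) {
  if (nrow(intervals) == 0) return(intervals)
  ot <- as.numeric(other_events$timestamp_utc)
  conf <- vapply(seq_len(nrow(intervals)), function(i) {
    e <- as.numeric(intervals$end[i])
    any(ot >= e & ot <= e + confirm_window * 60)
  }, logical(1))
  mutate(intervals, confirmed_end = conf)
}

#' Count daily (and nightly) visits from presence detections
#'
#' Clusters consecutive `detect` events separated by less than `visit_gap`
#' minutes into single visits; a visit's date is the local date of its first
#' detection. Days between the first and last observed date with no visits
#' are reported as zero (not missing). Night counts are visits whose first
#' detection falls inside `night_window` (local time, half-open).
#'
#' @param events Toilet (or PIR) `detect` events.
#' @param visit_gap Gap in minutes below which detections merge into one
#'   visit (default 5).
#' @param timezone IANA timezone for local dates.
#' @param night_window Character vector `c(start, end)` of local times
#'   `"HH:MM"`, default `c("00:00", "06:00")`.
#' @return Tibble `date`, `count`, `night_count`.
#' @export
daily_visit_counts <- function(events, visit_gap = 5, timezone = "UTC",
                               night_window = c("00:00", "06:00")) {
  ev <- events
  if (any(ev$event != "detect")) {
    abort("`daily_visit_counts()` expects `detect` events only.")
  }
  if (nrow(ev) == 0) {
    return(tibble(date = as.Date(character()), count = integer(),
                  night_count = integer()))
  }
  ev <- arrange(ev, .data$timestamp_utc)
  ts <- as.numeric(ev$timestamp_utc)
  new_visit <- c(TRUE, diff(ts) >= visit_gap * 60)
  first_ts <- ev$timestamp_utc[new_visit]
  local <- lubridate::with_tz(first_ts, timezone)
  vdate <- as.Date(local, tz = timezone)
  mins <- lubridate::hour(local) * 60 + lubridate::minute(local)
  nw <- vapply(strsplit(night_window, ":"), function(x) {
    as.numeric(x[1]) * 60 + as.numeric(x[2])
  }, numeric(1))
  is_night <- if (nw[1] <= nw[2]) mins >= nw[1] & mins < nw[2] else mins >= nw[1] | mins < nw[2]
  all_days <- seq(min(vdate), max(vdate), by = "day")
  visits <- tibble(date = vdate, night = is_night) |>
    group_by(.data$date) |>
    summarise(count = dplyr::n(), night_count = sum(.data$night), .groups = "drop")
  tibble(date = all_days) |>
    left_join(visits, by = "date") |>
    mutate(count = as.integer(ifelse(is.na(.data$count), 0L, .data$count)),
           night_count = as.integer(ifelse(is.na(.data$night_count), 0L, .data$night_count)))
}

events_to_intervals <- function(events) {
  # strict on/off pairing, no gap merging, no duration filter
  suppressWarnings(sessionize(events, gap_merge = 0, min_rest_duration = 0))
}

#' Bin one local day of presence into a binary trace
#'
#' Divides the local day into half-open bins of `bin_width` minutes and
#' marks bin `j` active (1) when the total presence time inside it reaches
#' at least `tmin` minutes. Bins are aligned to the local clock; on
#' daylight-saving transition days the physically observed bins are mapped
#' onto the canonical labels ([bin_labels()]): skipped bins are `NA`,
#' repeated bins are collapsed by logical OR.
#'
#' @param x Either a rest-interval tibble (`start`, `end`) or an on/off
#'   event tibble (paired internally without merging).
#' @param date Local calendar date to bin.
#' @param bin_width Bin width in minutes (default 30; must divide 1440).
#' @param tmin Minimum active minutes for a positive bin (default 5; must
#'   not exceed `bin_width`).
#' @param timezone IANA timezone defining the local day.
#' @return One-row `day_traces` tibble.
#' @seealso [bin_day_traces()] for a range of days.
#' @export
bin_day_trace <- function(x, date, bin_width = 30, tmin = 5, timezone = "UTC") {
  bin_day_traces(x, dates = as.Date(date), bin_width = bin_width,
                 tmin = tmin, timezone = timezone)
}

#' @rdname bin_day_trace
#' @param dates Vector of local dates; defaults to all dates touched by `x`.
#' @export
bin_day_traces <- function(x, dates = NULL, bin_width = 30, tmin = 5,
                           timezone = "UTC") {
  check_bin_width(bin_width)
  if (tmin > bin_width) abort("`tmin` must not exceed `bin_width`.")
  if ("event" %in% names(x)) x <- events_to_intervals(x)
  if (is.null(dates)) {
    if (nrow(x) == 0) abort("no intervals and no `dates` given.")
    d0 <- as.Date(lubridate::with_tz(min(x$start), timezone), tz = timezone)
    d1 <- as.Date(lubridate::with_tz(max(x$end), timezone), tz = timezone)
    dates <- seq(d0, d1, by = "day")
  }
  labs <- bin_labels(bin_width)
  s <- as.numeric(x$start)
  e <- as.numeric(x$end)
  mat <- matrix(NA_real_, nrow = length(dates), ncol = length(labs),
                dimnames = list(NULL, labs))
  for (r in seq_along(dates)) {
    day0 <- lubridate::force_tz(as.POSIXct(paste(dates[r], "00:00:00"), tz = "UTC"), timezone)
    day1 <- lubridate::force_tz(as.POSIXct(paste(dates[r] + 1, "00:00:00"), tz = "UTC"), timezone)
    bounds <- seq(as.numeric(day0), as.numeric(day1), by = bin_width * 60)
    nb <- length(bounds) - 1L
    act <- numeric(nb)
    if (length(s) > 0) {
      for (j in seq_len(nb)) {
        ov <- pmin(e, bounds[j + 1]) - pmax(s, bounds[j])
        act[j] <- sum(pmax(0, ov)) / 60
      }
    }
    blab <- format(lubridate::as_datetime(bounds[-length(bounds)], tz = timezone), "%H:%M")
    vals <- as.numeric(act >= tmin)
    row <- rep(NA_real_, length(labs))
    for (j in seq_len(nb)) {
      k <- match(blab[j], labs)
      if (is.na(k)) next
      row[k] <- max(row[k], vals[j], na.rm = TRUE)
    }
    mat[r, ] <- row
  }
  new_day_traces(dates, mat, bin_width, timezone)
}

#' Summarize transmission quality
#'
#' Report arithmetic over per-day transmission behavior: the share of
#' "ideal" days (all scheduled bursts completed on time) and of days with
#' "severe" issues (delivery delayed beyond the local buffer capacity).
#' Following a conservative reporting convention, the favorable percentage
#' is truncated to one decimal (never overstated) while the severe
#' percentage is rounded to two decimals.
#'
#' @param n_total_days Total sensor usage days (> 0).
#' @param n_ideal_days Days with all scheduled transmissions completed.
#' @param n_severe_days Days whose transmission issues exceeded the buffer.
#' @return One-row tibble with the counts, `pct_ideal` and `pct_severe`.
#' @export
#' @examples
#' transmission_quality(8970, 8231, 17)
transmission_quality <- function(n_total_days, n_ideal_days, n_severe_days) {
  if (n_total_days <= 0) abort("`n_total_days` must be positive.")
  if (n_ideal_days < 0 || n_ideal_days > n_total_days ||
      n_severe_days < 0 || n_severe_days > n_total_days) {
    abort("day counts must lie in [0, n_total_days].")
  }
  tibble(
    n_total_days = as.integer(n_total_days),
    n_ideal_days = as.integer(n_ideal_days),
    n_severe_days = as.integer(n_severe_days),
    pct_ideal = floor(1000 * n_ideal_days / n_total_days) / 10,
    pct_severe = round(100 * n_severe_days / n_total_days, 2)
  )
}

#' Derive a transmission-quality summary from burst-tagged events
#'
#' Classifies each UTC day of an event stream by its delivery delays: a day
#' is ideal when every event was delivered by its first scheduled burst, and
#' severe when any delivery delay exceeded `buffer_hours`.
#'
#' @param events Burst-tagged events (see [inject_transmission_schedule()]).
#' @param period_hours Burst period in hours.
#' @param buffer_hours Buffer capacity in hours (default 24).
#' @return A [transmission_quality()] tibble.
#' @export
summarize_transmission <- function(events, period_hours = 1, buffer_hours = 24) {
  if (nrow(events) == 0 || all(is.na(events$burst_id))) {
    abort("events carry no burst tags; nothing to summarize.")
  }
  per <- period_hours * 3600
  ts <- as.numeric(events$timestamp_utc)
  scheduled <- (floor(ts / per) + 1) * per
  burst <- as.numeric(as.POSIXct(events$burst_id, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  delay <- burst - scheduled
  day <- as.Date(lubridate::as_datetime(events$timestamp_utc, tz = "UTC"))
  per_day <- tibble(day = day, delay = delay) |>
    group_by(.data$day) |>
    summarise(max_delay = max(.data$delay), .groups = "drop")
  transmission_quality(
    n_total_days = nrow(per_day),
    n_ideal_days = sum(per_day$max_delay <= 0),
    n_severe_days = sum(per_day$max_delay > buffer_hours * 3600)
  )
}
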