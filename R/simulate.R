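#' Define a daily behavioral mode
#'
#' A mode is a per-bin Bernoulli probability vector describing one recurrent
#' daily presence routine (e.g., night-only sleep vs. night sleep plus an
#' afternoon nap), together with a mixing weight. Days simulated from a mode
#' set first pick a mode by weight, then draw each bin independently.
#'
#' @param name Text label for the mode.
#' @param bin_probabilities Numeric vector of per-bin activation
#'   probabilities in \[0, 1\]; length must be `1440 / bin_width` for the bin
#'   width in use.
#' @param weight Mixing proportion in \[0, 1\]. Weights of a mode set must
#'   sum to 1.
#' @return An object of class `mode_spec`.
#' @seealso [sleep_mode_presets()], [sample_day_traces()]
#' @export
mode_spec <- function(name, bin_probabilities, weight) {
  if (!is.character(name) || length(name) != 1 || is.na(name)) {
    abort("`name` must be a single string.")
  }
  p <- as.numeric(bin_probabilities)
  if (length(p) == 0 || anyNA(p) || any(p < 0 | p > 1)) {
    abort(sprintf("mode '%s': bin probabilities must all lie in [0, 1].", name))
  }
  if (length(weight) != 1 || is.na(weight) || weight < 0 || weight > 1) {
    abort(sprintf("mode '%s': weight must be a single value in [0, 1].", name))
  }
  structure(list(name = name, bin_probabilities = p, weight = as.numeric(weight)),
            class = "mode_spec")
}

#' Preset sleep modes and a deviant daytime pattern
#'
#' Two presence modes emulating the routines seen in multi-week bed-sensor
#' pilots: both modes sleep roughly 21:30--07:00 local time; the second adds
#' an early-afternoon nap (13:30--15:00). `deviant_daytime_probs()` returns a
#' probability vector belonging to neither mode (long daytime bed presence,
#' disturbed night), useful as a labeled positive class for novelty
#' detection.
#'
#' @param bin_width Bin width in minutes (default 30).
#' @param p_sleep Activation probability inside sleep/nap windows.
#' @param p_background Activation probability elsewhere.
#' @param weights Mixing weights for (night-only, night-plus-nap).
#' @return For `sleep_mode_presets()`, a list of two [mode_spec()] objects;
#'   for `deviant_daytime_probs()`, a numeric probability vector.
#' @export
sleep_mode_presets <- function(bin_width = 30, p_sleep = 0.95,
                               p_background = 0.02, weights = c(0.6, 0.4)) {
  labs <- bin_labels(bin_width)
  mins <- seq(0, 1439, by = bin_width)
  night <- mins >= 21.5 * 60 | mins < 7 * 60
  nap <- mins >= 13.5 * 60 & mins < 15 * 60
  p1 <- ifelse(night, p_sleep, p_background)
  p2 <- ifelse(night | nap, ifelse(nap, 0.9, p_sleep), p_background)
  list(
    mode_spec("night-only", p1, weights[1]),
    mode_spec("night-plus-nap", p2, weights[2])
  )
}

#' @describeIn sleep_mode_presets Well-separated variant used for recovery
#'   validation: longer nap (13:00--16:00), higher in-window probability
#'   (0.98) and lower background noise (0.005), so the between-mode cosine
#'   distance dominates within-mode day-to-day noise by a factor of about
#'   four and mode labels are recoverable exactly.
#' @export
well_separated_modes <- function(bin_width = 30, weights = c(0.5, 0.5)) {
  mins <- seq(0, 1439, by = bin_width)
  night <- mins >= 21.5 * 60 | mins < 7 * 60
  nap <- mins >= 13 * 60 & mins < 16 * 60
  p1 <- ifelse(night, 0.98, 0.005)
  p2 <- ifelse(night, 0.98, ifelse(nap, 0.95, 0.005))
  list(
    mode_spec("night-only", p1, weights[1]),
    mode_spec("night-plus-nap", p2, weights[2])
  )
}

#' @rdname sleep_mode_presets
#' @export
deviant_daytime_probs <- function(bin_width = 30) {
  mins <- seq(0, 1439, by = bin_width)
  day <- mins >= 9 * 60 & mins < 17 * 60
  night <- mins >= 21.5 * 60 | mins < 7 * 60
  ifelse(day, 0.9, ifelse(night, 0.3, 0.05))
}

#' Simulate daily presence traces from a set of behavioral modes
#'
#' Each day independently picks a mode according to the mixing weights, then
#' each time bin is an independent Bernoulli draw with that mode's bin
#' probability. Optionally, `n_deviant` randomly chosen days are instead
#' drawn from `deviant_probs`, a probability vector belonging to no mode;
#' these days are recorded in the ground truth so downstream novelty
#' detection can be scored against known labels.
#'
#' @param modes List of [mode_spec()] objects; weights must sum to 1 and all
#'   modes must share a bin count.
#' @param n_days Number of days to simulate.
#' @param seed Integer seed; identical seeds and parameters give identical
#'   output.
#' @param start_date First simulated date.
#' @param timezone IANA timezone of the simulated household.
#' @param deviant_probs Optional per-bin probability vector for deviant days.
#' @param n_deviant Number of deviant days to inject (default 0).
#' @return A list with elements `traces` (a [new_day_traces()] tibble) and
#'   `truth` (a `ground_truth` list with `mode_labels`, `deviant_days`,
#'   `severe_failure_days`, `expected_rates`).
#' @export
#' @examples
#' modes <- sleep_mode_presets()
#' sim <- sample_day_traces(modes, n_days = 10, seed = 1)
#' sim$truth$mode_labels
sample_day_traces <- function(modes, n_days, seed,
                              start_date = as.Date("2024-01-01"),
                              timezone = "UTC",
                              deviant_probs = NULL, n_deviant = 0) {
  if (length(modes) == 0) abort("at least one mode is required.")
  modes <- lapply(modes, function(m) {
    if (!inherits(m, "mode_spec")) abort("all modes must be `mode_spec` objects.")
    m
  })
  nb <- length(modes[[1]]$bin_probabilities)
  for (m in modes) {
    if (length(m$bin_probabilities) != nb) {
      abort(sprintf("mode '%s' has %d bins; expected %d like the first mode.",
                    m$name, length(m$bin_probabilities), nb))
    }
  }
  w <- vapply(modes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) abort("mode weights must sum to 1.")
  if (1440 %% nb != 0) abort("bin count must divide 1440 minutes.")
  bin_width <- 1440 / nb
  if (n_deviant > 0 && is.null(deviant_probs)) {
    abort("`deviant_probs` is required when `n_deviant` > 0.")
  }
  if (!is.null(deviant_probs) && length(deviant_probs) != nb) {
    abort("`deviant_probs` must have the same bin count as the modes.")
  }

  dates <- as.Date(start_date) + seq_len(n_days) - 1L
  out <- withr::with_seed(seed, {
    idx <- sample.int(length(modes), n_days, replace = TRUE, prob = w)
    mat <- t(vapply(idx, function(i) {
      rbinom(nb, 1L, modes[[i]]$bin_probabilities)
    }, integer(nb)))
    dev_rows <- integer(0)
    if (n_deviant > 0) {
      dev_rows <- sort(sample.int(n_days, n_deviant))
      for (r in dev_rows) mat[r, ] <- rbinom(nb, 1L, deviant_probs)
    }
    list(idx = idx, mat = mat, dev_rows = dev_rows)
  })
  labels <- vapply(modes, `[[`, character(1), "name")[out$idx]
  labels[out$dev_rows] <- "deviant"
  truth <- new_ground_truth(
    mode_labels = tibble(date = dates, mode = labels),
    deviant_days = dates[out$dev_rows]
  )
  list(traces = new_day_traces(dates, out$mat, bin_width, timezone),
       truth = truth)
}

new_ground_truth <- function(mode_labels = NULL, deviant_days = as.Date(character()),
                             severe_failure_days = as.Date(character()),
                             expected_rates = NULL) {
  structure(list(mode_labels = mode_labels,
                 deviant_days = deviant_days,
                 severe_failure_days = severe_failure_days,
                 expected_rates = expected_rates),
            class = "ground_truth")
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth A `ground_truth` object from a simulator function.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  payload <- list(
    mode_labels = truth$mode_labels,
    deviant_days = as.character(truth$deviant_days),
    severe_failure_days = as.character(truth$severe_failure_days),
    expected_rates = truth$expected_rates
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Define a daily-count simulation scenario
#'
#' Describes the generative model for a daily visit-count series: day `d`
#' (1-based) has Poisson mean
#' `baseline_rate * exp(linear_log_slope * (d - 1) / (n_days - 1)) *
#'  exp(abrupt_log_effect * [d >= abrupt_start_day]) * outlier multiplier`.
#' This mirrors the covariate structure of the rolling trend model, so
#' parameter recovery is well-posed.
#'
#' @param n_days Number of days.
#' @param baseline_rate Expected daily count at baseline (> 0).
#' @param linear_log_slope Log fold-change accumulated linearly over the
#'   whole period (0 = no drift).
#' @param abrupt_start_day Day index (1-based) at which a step change starts,
#'   or `NULL` for none.
#' @param abrupt_log_effect Log multiplier applied from `abrupt_start_day`
#'   onwards.
#' @param outlier_days Named numeric vector mapping day index to a positive
#'   multiplier for isolated outlier days, or `NULL`.
#' @param seed Integer seed.
#' @return An object of class `count_scenario`.
#' @export
count_scenario <- function(n_days, baseline_rate, linear_log_slope = 0,
                           abrupt_start_day = NULL, abrupt_log_effect = 0,
                           outlier_days = NULL, seed = 1) {
  if (n_days < 1) abort("`n_days` must be a positive integer.")
  if (baseline_rate <= 0) abort("`baseline_rate` must be > 0.")
  if (!is.null(abrupt_start_day) &&
      (abrupt_start_day < 1 || abrupt_start_day > n_days)) {
    abort("`abrupt_start_day` must lie in 1..n_days.")
  }
  if (!is.null(outlier_days)) {
    if (is.null(names(outlier_days)) || anyNA(suppressWarnings(as.integer(names(outlier_days))))) {
      abort("`outlier_days` must be a named vector, names = day indices.")
    }
    if (any(outlier_days <= 0)) abort("outlier multipliers must be > 0.")
  }
  structure(list(n_days = as.integer(n_days),
                 baseline_rate = baseline_rate,
                 linear_log_slope = linear_log_slope,
                 abrupt_start_day = if (is.null(abrupt_start_day)) NULL else as.integer(abrupt_start_day),
                 abrupt_log_effect = abrupt_log_effect,
                 outlier_days = outlier_days,
                 seed = as.integer(seed)),
            class = "count_scenario")
}

#' Simulate a daily visit-count series
#'
#' Draws independent Poisson counts with the per-day means defined by a
#' [count_scenario()]. The realized means are stored in the ground truth so
#' trend-recovery tests can compare estimates to the generative values.
#'
#' @param scenario A [count_scenario()].
#' @param start_date First date of the series.
#' @return A list with `counts` (tibble `date`, `count`) and `truth`
#'   (a `ground_truth` whose `expected_rates` holds the per-day means).
#' @export
#' @examples
#' sc <- count_scenario(30, baseline_rate = 4, abrupt_start_day = 26,
#'                      abrupt_log_effect = log(2), seed = 7)
#' sim <- simulate_daily_counts(sc)
#' tail(sim$truth$expected_rates)
simulate_daily_counts <- function(scenario, start_date = as.Date("2024-01-01")) {
  stopifnot(inherits(scenario, "count_scenario"))
  n <- scenario$n_days
  d <- seq_len(n)
  frac <- if (n > 1) (d - 1) / (n - 1) else rep(0, n)
  log_mu <- log(scenario$baseline_rate) + scenario$linear_log_slope * frac
  if (!is.null(scenario$abrupt_start_day)) {
    log_mu <- log_mu + scenario$abrupt_log_effect * (d >= scenario$abrupt_start_day)
  }
  mu <- exp(log_mu)
  if (!is.null(scenario$outlier_days)) {
    idx <- as.integer(names(scenario$outlier_days))
    mu[idx] <- mu[idx] * as.numeric(scenario$outlier_days)
  }
  counts <- withr::with_seed(scenario$seed, rpois(n, mu))
  dates <- as.Date(start_date) + d - 1L
  truth <- new_ground_truth(
    expected_rates = tibble(date = dates, rate = mu)
  )
  list(counts = tibble(date = dates, count = counts), truth = truth)
}

#' Expand day traces into a raw sensor event stream
#'
#' The inverse of [bin_day_trace()]: for every active bin an on/off event
#' pair covering `fill_fraction` of the bin is emitted (onset placed
#' uniformly at random within the slack when `fill_fraction < 1`).
#' Contiguous active bins with `fill_fraction = 1` collapse into a single
#' on/off pair. Round-tripping through [bin_day_traces()] with the same bin
#' width and `tmin <= fill_fraction * bin_width` recovers the input traces
#' exactly.
#'
#' @param traces A `day_traces` tibble.
#' @param sensor_id Sensor identifier written into the events.
#' @param sensor_type One of `"bed"`, `"chair"`, `"contact"`.
#' @param fill_fraction Fraction of each active bin covered by presence,
#'   in (0, 1].
#' @param seed Integer seed for onset jitter.
#' @param tmin Optional downstream activation threshold (minutes); a warning
#'   is raised if `fill_fraction * bin_width < tmin` (round trip not
#'   guaranteed).
#' @return A sensor-event tibble (`timestamp_utc`, `sensor_id`,
#'   `sensor_type`, `event`, `burst_id`), sorted by time.
#' @export
traces_to_events <- function(traces, sensor_id = "bed-1", sensor_type = "bed",
                             fill_fraction = 1, seed = 1, tmin = NULL) {
  if (fill_fraction <= 0 || fill_fraction > 1) {
    abort("`fill_fraction` must lie in (0, 1].")
  }
  bw <- trace_bin_width(traces)
  tz <- trace_timezone(traces)
  if (!is.null(tmin) && fill_fraction * bw < tmin) {
    warn(sprintf(paste0("fill_fraction * bin_width = %.1f min is below tmin = %s min; ",
                        "round-trip recovery is not guaranteed."),
                 fill_fraction * bw, tmin))
  }
  mat <- trace_matrix(traces)
  labs <- colnames(mat)
  n_bins <- ncol(mat)
  starts_ends <- withr::with_seed(seed, {
    out_start <- list(); out_end <- list(); k <- 0
    for (r in seq_len(nrow(mat))) {
      day <- traces$date[r]
      bstart <- lubridate::force_tz(as.POSIXct(paste(day, labs), tz = "UTC"), tz)
      active <- which(!is.na(mat[r, ]) & mat[r, ] == 1 & !is.na(bstart))
      if (length(active) == 0) next
      slack <- (1 - fill_fraction) * bw * 60
      offs <- if (slack > 0) runif(length(active), 0, slack) else rep(0, length(active))
      on <- bstart[active] + offs
      off <- on + fill_fraction * bw * 60
      # merge back-to-back pairs (fully filled contiguous bins)
      keep_on <- c(TRUE, as.numeric(on[-1]) != as.numeric(off[-length(off)]))
      keep_off <- c(keep_on[-1], TRUE)
      k <- k + 1
      out_start[[k]] <- on[keep_on]
      out_end[[k]] <- off[keep_off]
    }
    list(on = out_start, off = out_end)
  })
  ons <- lubridate::with_tz(do.call(c, c(starts_ends$on, list(as.POSIXct(character(), tz = "UTC")))), "UTC")
  offs <- lubridate::with_tz(do.call(c, c(starts_ends$off, list(as.POSIXct(character(), tz = "UTC")))), "UTC")
  ev <- tibble(
    timestamp_utc = c(ons, offs),
    sensor_id = sensor_id,
    sensor_type = sensor_type,
    event = rep(c("on", "off"), c(length(ons), length(offs))),
    burst_id = NA_character_
  )
  # at equal timestamps "off" sorts first so midnight-adjacent runs pair cleanly
  arrange(ev, .data$timestamp_utc, .data$event == "on")
}

#' Expand a daily-count series into presence-detection events
#'
#' The inverse of [daily_visit_counts()]: each counted visit becomes a
#' short burst of `detections_per_visit` detect events (1 minute apart),
#' with visits spaced `visit_spacing` minutes starting at `first_visit`
#' local time. Round-tripping through [daily_visit_counts()] with a
#' `visit_gap` below `visit_spacing` recovers the counts exactly.
#'
#' @param counts Tibble with `date` and `count` columns.
#' @param sensor_id,sensor_type Identifier fields for the emitted events.
#' @param timezone IANA timezone for local visit times.
#' @param first_visit Local clock time `"HH:MM"` of the first visit.
#' @param visit_spacing Minutes between visit starts (default 35).
#' @param detections_per_visit Detect events per visit (default 2).
#' @return Sensor-event tibble sorted by time.
#' @export
counts_to_events <- function(counts, sensor_id = "toilet-1",
                             sensor_type = "toilet", timezone = "UTC",
                             first_visit = "06:00", visit_spacing = 35,
                             detections_per_visit = 2) {
  stopifnot(all(c("date", "count") %in% names(counts)))
  if (any(counts$count * visit_spacing > 1380)) {
    abort("daily count too large for the visit spacing; visits would spill past midnight.")
  }
  rows <- purrr::pmap(list(counts$date, counts$count), function(day, k) {
    if (k == 0) return(NULL)
    base <- lubridate::force_tz(
      as.POSIXct(paste(day, first_visit), tz = "UTC"), timezone)
    starts <- base + (seq_len(k) - 1) * visit_spacing * 60
    dets <- rep(starts, each = detections_per_visit) +
      rep(seq_len(detections_per_visit) - 1, times = k) * 60
    tibble(timestamp_utc = lubridate::with_tz(dets, "UTC"))
  })
  det <- list_rbind(purrr::compact(rows))
  if (nrow(det) == 0) {
    return(tibble(timestamp_utc = as.POSIXct(character(), tz = "UTC"),
                  sensor_id = character(), sensor_type = character(),
                  event = character(), burst_id = character()))
  }
  arrange(tibble(timestamp_utc = det$timestamp_utc, sensor_id = sensor_id,
                 sensor_type = sensor_type, event = "detect",
                 burst_id = NA_character_), .data$timestamp_utc)
}

#' Tag events with a periodic transmission schedule and inject failures
#'
#' Sensors buffer events locally and transmit them in periodic bursts. Each
#' event is tagged with the timestamp of the burst that delivered it:
#' normally the first scheduled boundary after the event. On `missed_days`
#' at least one scheduled burst fails and the day's events are delivered
#' late (but within the one-day local buffer); on `severe_days` (a subset)
#' the delay exceeds the buffer, which downstream quality reporting counts
#' as a severe transmission issue. Payloads are always preserved; severity
#' is encoded purely in delivery delay.
#'
#' @param events Sensor-event tibble.
#' @param period_hours Burst period in hours (default 1).
#' @param missed_days Vector of dates with at least one missed burst.
#' @param severe_days Subset of `missed_days` whose delay exceeds the buffer.
#' @param seed Integer seed for the delay draws.
#' @param buffer_hours Local buffer capacity in hours (default 24).
#' @return List with `events` (burst-tagged) and `truth` (ground truth with
#'   `severe_failure_days`).
#' @export
inject_transmission_schedule <- function(events, period_hours = 1,
                                         missed_days = NULL, severe_days = NULL,
                                         seed = 1, buffer_hours = 24) {
  missed_days <- as.Date(missed_days %||% as.Date(character()))
  severe_days <- as.Date(severe_days %||% as.Date(character()))
  if (!all(severe_days %in% missed_days)) {
    abort("`severe_days` must be a subset of `missed_days`.")
  }
  per <- period_hours * 3600
  ts <- as.numeric(events$timestamp_utc)
  scheduled <- (floor(ts / per) + 1) * per
  day <- as.Date(lubridate::as_datetime(events$timestamp_utc, tz = "UTC"))
  delay <- withr::with_seed(seed, {
    d <- rep(0, nrow(events))
    for (md in missed_days) {
      in_day <- day == md
      if (!any(in_day)) next
      if (as.Date(md, origin = "1970-01-01") %in% severe_days) {
        d[in_day] <- buffer_hours * 3600 + sample.int(24, 1) * 3600
      } else {
        max_k <- max(1, floor(buffer_hours / period_hours) - 1)
        d[in_day] <- sample.int(max_k, 1) * per
      }
    }
    d
  })
  burst <- lubridate::as_datetime(scheduled + delay, tz = "UTC")
  ev <- mutate(events, burst_id = format(burst, "%Y-%m-%dT%H:%M:%SZ"))
  truth <- new_ground_truth(severe_failure_days = sort(severe_days))
  list(events = ev, truth = truth)
}
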