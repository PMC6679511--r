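#' Assemble and validate a pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis, validates
#' each against its module's preconditions before any stage runs, and
#' returns a `pipeline_config` object. All parameters have the package
#' defaults; any can be overridden.
#'
#' @param events Path to the input event CSV (see [read_events()]).
#' @param subject Pseudonymous subject identifier echoed into the report.
#' @param timezone IANA timezone of the household.
#' @param bin_width,tmin Day-trace binning parameters (minutes).
#' @param window,abrupt,intermediate,alpha,level Trend-model parameters
#'   (see [design_spec()]).
#' @param n_sam,k_max Clustering parameters (see [cluster_day_traces()]).
#' @param epsilon Novelty clip bound, or `NULL` for the automatic default.
#' @param visit_gap,gap_merge,min_rest_duration,confirm_window Event
#'   preprocessing parameters (minutes).
#' @param night_window Local-time night window `c(start, end)`.
#' @param period_hours Transmission burst period (hours).
#' @param seed Integer seed echoed to every stochastic stage.
#' @param out_dir Output directory for the report files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(events, subject = "anonymous", timezone = "UTC",
                            bin_width = 30, tmin = 5,
                            window = 30, abrupt = 5, intermediate = 10,
                            alpha = 0.05, level = 0.95,
                            n_sam = 5, k_max = 8, epsilon = NULL,
                            visit_gap = 5, gap_merge = 15,
                            min_rest_duration = 10, confirm_window = 10,
                            night_window = c("00:00", "06:00"),
                            period_hours = 1, seed = 1, out_dir = NULL) {
  check_bin_width(bin_width)
  if (tmin > bin_width) abort("`tmin` must not exceed `bin_width`.")
  spec <- design_spec(window, abrupt, intermediate, alpha, level) # validates
  if (n_sam < 1) abort("`n_sam` must be at least 1.")
  if (k_max < 2) abort("`k_max` must be at least 2.")
  if (!is.null(epsilon) && (epsilon <= 0 || epsilon >= 0.5)) {
    abort("`epsilon` must lie in (0, 0.5).")
  }
  for (nm in c("visit_gap", "gap_merge", "min_rest_duration", "confirm_window")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      abort(sprintf("`%s` must be a single non-negative number of minutes.", nm))
    }
  }
  structure(list(
    events = events, subject = subject, timezone = timezone,
    bin_width = bin_width, tmin = tmin, spec = spec,
    n_sam = n_sam, k_max = k_max, epsilon = epsilon,
    visit_gap = visit_gap, gap_merge = gap_merge,
    min_rest_duration = min_rest_duration, confirm_window = confirm_window,
    night_window = night_window, period_hours = period_hours,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat-key YAML; keys are the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$night_window)) cfg$night_window <- as.character(cfg$night_window)
  do.call(pipeline_config, cfg)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

log_stage <- function(name, msg) {
  message(sprintf("[%s] %s", name, msg))
}

#' Run the full behavioral-analysis pipeline
#'
#' Reads an event log and produces the caregiver-facing synthesis: daily
#' toilet-count trend analysis (alerts, percent effects, unexplained days),
#' bed-rest Sensor Profiles with mode clustering and novelty flags, and a
#' transmission-quality summary. The report carries only derived summaries
#' -- never raw event payloads -- and echoes every stage parameter for
#' provenance. Output is deterministic given the configuration (including
#' its seed).
#'
#' @param config A [pipeline_config()].
#' @return A `behavior_report` list; if `config$out_dir` is set, the report
#'   is also written as `report.json` and `report.txt` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ev <- stage("read_events", {
    e <- read_events(config$events)
    if (nrow(e) == 0) abort(sprintf("event file '%s' contains no events.", config$events))
    e
  })
  log_stage("read_events", sprintf("%d events from %s", nrow(ev), config$events))

  quality <- NULL
  if (any(!is.na(ev$burst_id))) {
    quality <- stage("transmission_quality",
                     summarize_transmission(ev, period_hours = config$period_hours))
    log_stage("transmission_quality",
              sprintf("%s%% ideal days", quality$pct_ideal))
  }

  trend_section <- NULL
  toilet <- filter(ev, .data$sensor_type == "toilet")
  if (nrow(toilet) > 0) {
    counts <- stage("daily_visit_counts",
                    daily_visit_counts(toilet, visit_gap = config$visit_gap,
                                       timezone = config$timezone,
                                       night_window = config$night_window))
    if (nrow(counts) >= config$spec$window) {
      rr <- stage("rolling_analysis", rolling_analysis(counts, config$spec))
      done <- filter(rr, !.data$skipped)
      trend_section <- list(
        n_days = nrow(counts),
        n_analysis_dates = nrow(rr),
        alert_dates = as.character(done$date[which(done$alert)]),
        unexplained_dates = as.character(done$date[which(done$unexplained)]),
        last_day = list(
          date = as.character(done$date[nrow(done)]),
          retained = done$retained[nrow(done)],
          abrupt_pct = done$abrupt_pct[nrow(done)],
          linear_pct = done$linear_pct[nrow(done)]
        )
      )
      log_stage("rolling_analysis",
                sprintf("%d alert day(s), %d unexplained day(s)",
                        length(trend_section$alert_dates),
                        length(trend_section$unexplained_dates)))
    }
  }

  profile_section <- NULL
  bed <- filter(ev, .data$sensor_type == "bed")
  if (nrow(bed) > 0) {
    rests <- stage("sessionize",
                   sessionize(bed, gap_merge = config$gap_merge,
                              min_rest_duration = config$min_rest_duration))
    other <- filter(ev, .data$sensor_type %in% c("pir", "contact"))
    if (nrow(other) > 0) {
      rests <- stage("confirm_rest_end",
                     confirm_rest_end(rests, other, config$confirm_window))
    }
    traces <- stage("bin_day_traces",
                    bin_day_traces(rests, bin_width = config$bin_width,
                                   tmin = config$tmin,
                                   timezone = config$timezone))
    profile <- stage("estimate_profile", estimate_profile(traces))
    cl <- NULL; nov <- NULL
    if (nrow(traces) >= 2 * config$n_sam) {
      cl <- stage("cluster_day_traces",
                  cluster_day_traces(traces, n_sam = config$n_sam,
                                     k_max = config$k_max))
      nov <- stage("detect_novelty",
                   detect_novelty(traces, cl$prototypes[["1"]],
                                  epsilon = config$epsilon))
      log_stage("cluster_day_traces",
                sprintf("%d cluster(s), %d novelty outlier day(s)",
                        cl$n_clus, sum(nov$scores$outlier)))
    }
    profile_section <- list(
      n_days = nrow(traces),
      n_rest_intervals = nrow(rests),
      pct_confirmed_ends = if (nrow(rests) > 0) round(100 * mean(rests$confirmed_end), 1) else NA,
      profile = as_tibble(profile),
      n_clusters = if (is.null(cl)) NA_integer_ else cl$n_clus,
      silhouette = if (is.null(cl)) NA_real_ else cl$silhouette,
      cluster_sizes = if (is.null(cl)) NULL else as.list(table(cl$labels$assignment)),
      novelty_threshold = if (is.null(nov)) NA_real_ else nov$threshold,
      deviant_dates = if (is.null(nov)) character(0) else as.character(nov$scores$date[nov$scores$outlier]),
      deviant_ns = if (is.null(nov)) numeric(0) else nov$scores$ns[nov$scores$outlier]
    )
  }

  report <- structure(list(
    schema_version = "1.0",
    subject = config$subject,
    period = list(
      start = format(min(ev$timestamp_utc), "%Y-%m-%d"),
      end = format(max(ev$timestamp_utc), "%Y-%m-%d")
    ),
    parameters = config_parameters(config),
    quality = if (is.null(quality)) NULL else as.list(quality),
    trends = trend_section,
    profiles = profile_section
  ), class = "behavior_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, config$out_dir)
  }
  report
}

config_parameters <- function(config) {
  list(
    timezone = config$timezone, bin_width = config$bin_width,
    tmin = config$tmin, window = config$spec$window,
    abrupt = config$spec$abrupt, intermediate = config$spec$intermediate,
    alpha = config$spec$alpha, level = config$spec$level,
    n_sam = config$n_sam, k_max = config$k_max,
    epsilon = config$epsilon,
    visit_gap = config$visit_gap, gap_merge = config$gap_merge,
    min_rest_duration = config$min_rest_duration,
    confirm_window = config$confirm_window,
    night_window = config$night_window,
    period_hours = config$period_hours, seed = config$seed
  )
}

report_to_json_list <- function(report) {
  r <- unclass(report)
  if (!is.null(r$profiles$profile)) {
    r$profiles$profile <- as.data.frame(r$profiles$profile)
  }
  r
}

#' Write a behavior report to disk
#'
#' Writes `report.json` (machine-readable, schema in
#' `inst/extdata/report-schema.json`) and `report.txt` (human-readable
#' synthesis). Output bytes are deterministic for identical reports.
#'
#' @param report A `behavior_report` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_report <- function(report, out_dir) {
  json_path <- file.path(out_dir, "report.json")
  txt_path <- file.path(out_dir, "report.txt")
  jsonlite::write_json(report_to_json_list(report), json_path,
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  writeLines(format_report_text(report), txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

format_report_text <- function(report) {
  ln <- c(
    sprintf("Behavior report for subject %s", report$subject),
    sprintf("Period: %s to %s", report$period$start, report$period$end),
    ""
  )
  if (!is.null(report$quality)) {
    q <- report$quality
    ln <- c(ln, "Data quality:",
            sprintf("  %d sensor usage days; %.1f%% ideal, %.2f%% severe transmission issues",
                    q$n_total_days, q$pct_ideal, q$pct_severe), "")
  }
  if (!is.null(report$trends)) {
    t <- report$trends
    ln <- c(ln, "Toilet-usage trends:",
            sprintf("  %d days analyzed (%d analysis dates)", t$n_days, t$n_analysis_dates),
            sprintf("  alert dates: %s",
                    if (length(t$alert_dates)) paste(t$alert_dates, collapse = ", ") else "none"),
            sprintf("  unexplained dates: %s",
                    if (length(t$unexplained_dates)) paste(t$unexplained_dates, collapse = ", ") else "none"),
            "")
  }
  if (!is.null(report$profiles)) {
    p <- report$profiles
    ln <- c(ln, "Bed-rest habits:",
            sprintf("  %d days of traces from %d rest intervals", p$n_days, p$n_rest_intervals),
            sprintf("  behavioral modes: %s",
                    ifelse(is.na(p$n_clusters), "not assessed", p$n_clusters)),
            sprintf("  deviant days (novelty): %s",
                    if (length(p$deviant_dates)) paste(p$deviant_dates, collapse = ", ") else "none"),
            "")
  }
  ln
}

#' Structural validation of a behavior report
#'
#' Checks a report (or its parsed JSON) against the shipped schema's
#' required keys and basic types. This is a lightweight structural check,
#' not a full JSON-Schema validator.
#'
#' @param report A `behavior_report` or a list parsed from `report.json`.
#' @return `TRUE` invisibly; aborts with the first violation found.
#' @export
check_report <- function(report) {
  req <- c("schema_version", "subject", "period", "parameters")
  missing <- setdiff(req, names(report))
  if (length(missing) > 0) {
    abort(sprintf("report is missing required field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!is.character(report$subject) && !is.null(report$subject)) {
    abort("`subject` must be a string.")
  }
  if (!all(c("start", "end") %in% names(report$period))) {
    abort("`period` must contain `start` and `end`.")
  }
  par_req <- c("window", "abrupt", "intermediate", "alpha", "level",
               "bin_width", "tmin", "seed")
  pmissing <- setdiff(par_req, names(report$parameters))
  if (length(pmissing) > 0) {
    abort(sprintf("report parameters missing: %s", paste(pmissing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.behavior_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
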