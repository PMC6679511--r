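#' Rolling daily trend and anomaly analysis of a count series
#'
#' At each analysis date the trailing `window` daily counts are fitted with
#' the Poisson trend model after backward factor selection
#' ([backward_select()]); results are referenced to the last day of the
#' window. The last day's count is compared with the equal-tailed central
#' interval of its fitted mean: counts outside it are labeled
#' *unexplained*. An *alert* is raised whenever an abrupt or linear trend
#' factor is retained, and the trend is reported as a percent change
#' relative to the baseline. Advancing one day re-fits the model, so a
#' persisting behavioral change is absorbed into the model rather than
#' flagged repeatedly.
#'
#' @param counts Tibble with `date` and `count` columns (gaps in the date
#'   sequence become missing days).
#' @param spec A [design_spec()].
#' @param holdout_last If `TRUE`, the last day is excluded from the fit and
#'   scored under the model fitted on the preceding days; by default the
#'   last day is part of the fitted window.
#' @param min_days Minimum usable (non-missing) days a window needs; windows
#'   below it are marked `skipped` rather than fitted. Missing days inside
#'   an analyzed window are dropped from the likelihood, never imputed.
#' @param method Factor-selection method passed to [backward_select()].
#' @return A tibble of class `rolling_trend`, one row per analysis date:
#'   `date`, `skipped`, `converged`, `retained` (comma-joined), `mu_last`,
#'   `observed`, `lo`, `hi`, `unexplained`, `alert`, `abrupt_pct`,
#'   `linear_pct`, and a `fit` list-column of `poisson_trend_fit` objects.
#' @export
#' @examples
#' sim <- simulate_daily_counts(count_scenario(60, baseline_rate = 4, seed = 1))
#' res <- rolling_analysis(sim$counts)
#' glance(res)
rolling_analysis <- function(counts, spec = design_spec(),
                             holdout_last = FALSE, min_days = 20,
                             method = c("screen", "stepwise")) {
  method <- match.arg(method)
  stopifnot(all(c("date", "count") %in% names(counts)))
  counts <- arrange(counts, .data$date)
  all_dates <- seq(min(counts$date), max(counts$date), by = "day")
  y_full <- counts$count[match(all_dates, counts$date)]
  W <- spec$window
  if (length(all_dates) < W) {
    abort(sprintf("need at least %d days of record; got %d.", W, length(all_dates)))
  }
  design <- build_design(spec)
  rows <- map(W:length(all_dates), function(t) {
    idx <- (t - W + 1):t
    y <- y_full[idx]
    usable <- sum(!is.na(y))
    base <- tibble(date = all_dates[t], skipped = FALSE, converged = NA,
                   retained = NA_character_, mu_last = NA_real_,
                   observed = y[W], lo = NA_integer_, hi = NA_integer_,
                   unexplained = NA, alert = NA,
                   abrupt_pct = NA_real_, linear_pct = NA_real_,
                   fit = list(NULL))
    if (usable < min_days) {
      base$skipped <- TRUE
      return(base)
    }
    y_fit <- y
    if (holdout_last) y_fit[W] <- NA
    fit <- backward_select(y_fit, design, spec, method = method)
    mu_last <- fit$mu[W]
    ci <- poisson_central_interval(mu_last, spec$level)
    eff <- factor_effects(fit)
    trendy <- intersect(fit$retained, c("abrupt", "linear"))
    base$converged <- fit$converged
    base$retained <- paste(fit$retained, collapse = ",")
    base$mu_last <- mu_last
    base$lo <- as.integer(ci$lo)
    base$hi <- as.integer(ci$hi)
    base$unexplained <- if (is.na(y[W])) NA else (y[W] < ci$lo | y[W] > ci$hi)
    base$alert <- length(trendy) > 0
    if ("abrupt" %in% eff$term) {
      base$abrupt_pct <- eff$percent_change[eff$term == "abrupt"]
    }
    if ("linear" %in% eff$term) {
      base$linear_pct <- eff$percent_change[eff$term == "linear"]
    }
    base$fit <- list(fit)
    base
  })
  out <- list_rbind(rows)
  attr(out, "spec") <- spec
  class(out) <- c("rolling_trend", class(out))
  out
}

#' @export
tidy.rolling_trend <- function(x, ...) {
  keep <- !vapply(x$fit, is.null, logical(1))
  list_rbind(map(which(keep), function(i) {
    mutate(tidy(x$fit[[i]]), date = x$date[i], .before = 1)
  }))
}

#' @export
glance.rolling_trend <- function(x, ...) {
  done <- filter(x, !.data$skipped)
  tibble(
    n_dates = nrow(x),
    n_skipped = sum(x$skipped),
    n_alerts = sum(done$alert, na.rm = TRUE),
    n_unexplained = sum(done$unexplained, na.rm = TRUE),
    first_alert = if (any(done$alert, na.rm = TRUE)) min(done$date[which(done$alert)]) else as.Date(NA)
  )
}

#' @export
autoplot.rolling_trend <- function(object, counts = NULL, ...) {
  dat <- filter(object, !.data$skipped)
  p <- ggplot(dat, aes(x = .data$date)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "steelblue",
                alpha = 0.15) +
    geom_line(aes(y = .data$mu_last), color = "steelblue", linetype = "dotted") +
    geom_point(aes(y = .data$observed, color = .data$unexplained), size = 1.5) +
    scale_color_manual(values = c(`FALSE` = "grey30", `TRUE` = "red"),
                       na.value = "grey70", name = "unexplained") +
    labs(x = NULL, y = "daily count",
         title = "Rolling Poisson trend analysis",
         subtitle = "dotted: fitted mean; ribbon: central interval; red: unexplained days") +
    theme_minimal()
  if (any(dat$alert, na.rm = TRUE)) {
    p <- p + geom_rug(data = filter(dat, .data$alert), sides = "b",
                      color = "darkorange")
  }
  p
}
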