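#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson score bounds; well behaved for proportions near 0 or
#' 1 at small sample sizes, which is typical of per-bin presence estimates.
#'
#' @param x Positive-outcome counts.
#' @param n Trial counts (same length or scalar).
#' @param level Confidence level (default 0.95).
#' @return Tibble `low`, `high`.
#' @export
wilson_interval <- function(x, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  low <- pmax(0, center - half)
  high <- pmin(1, center + half)
  low[x == 0] <- 0 # exact bounds at the degenerate corners
  high[x == n] <- 1
  tibble(low = low, high = high)
}

#' Clopper--Pearson (exact) interval for a binomial proportion
#'
#' @inheritParams wilson_interval
#' @return Tibble `low`, `high`.
#' @export
clopper_pearson_interval <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  low <- ifelse(x == 0, 0, qbeta(a, x, n - x + 1))
  high <- ifelse(x == n, 1, qbeta(1 - a, x + 1, n - x))
  tibble(low = low, high = high)
}

#' Estimate a Sensor Profile from day traces
#'
#' For each time bin, the probability of the sensor being active in that
#' bin is the maximum-likelihood Bernoulli estimate `p_hat = n_pos / N`
#' over the observed days, with a confidence interval attached. `NA` bins
#' (daylight-saving gaps) are excluded from that bin's denominator.
#'
#' @param traces A `day_traces` tibble with at least one day.
#' @param ci Interval method, `"wilson"` (default) or `"clopper-pearson"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble of class `sensor_profile`: `bin`, `n_pos`, `n_total`,
#'   `p_hat`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' sim <- sample_day_traces(sleep_mode_presets(), n_days = 30, seed = 2)
#' estimate_profile(sim$traces)
estimate_profile <- function(traces, ci = c("wilson", "clopper-pearson"),
                             level = 0.95) {
  ci <- match.arg(ci)
  if (!is.data.frame(traces) || nrow(traces) == 0) {
    abort("`traces` must contain at least one day.")
  }
  m <- trace_matrix(traces)
  n_pos <- colSums(m == 1, na.rm = TRUE)
  n_total <- colSums(!is.na(m))
  p_hat <- ifelse(n_total > 0, n_pos / n_total, NA_real_)
  bounds <- if (ci == "wilson") {
    wilson_interval(n_pos, pmax(n_total, 1), level)
  } else {
    clopper_pearson_interval(n_pos, pmax(n_total, 1), level)
  }
  out <- tibble(
    bin = colnames(m),
    n_pos = as.integer(unname(n_pos)),
    n_total = as.integer(unname(n_total)),
    p_hat = unname(p_hat),
    ci_low = unname(ifelse(n_total > 0, bounds$low, NA_real_)),
    ci_high = unname(ifelse(n_total > 0, bounds$high, NA_real_))
  )
  attr(out, "bin_width") <- trace_bin_width(traces)
  attr(out, "level") <- level
  attr(out, "ci_method") <- ci
  class(out) <- c("sensor_profile", class(out))
  out
}

#' @export
glance.sensor_profile <- function(x, ...) {
  tibble(n_bins = nrow(x), n_days = max(x$n_total),
         mean_p = mean(x$p_hat, na.rm = TRUE),
         ci_method = attr(x, "ci_method") %||% "wilson")
}

#' @export
autoplot.sensor_profile <- function(object, ...) {
  hrs <- vapply(strsplit(object$bin, ":"), function(v) {
    as.numeric(v[1]) + as.numeric(v[2]) / 60
  }, numeric(1))
  dat <- mutate(as_tibble(object), hour = hrs)
  ggplot(dat, aes(x = .data$hour)) +
    geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                fill = "steelblue", alpha = 0.25) +
    geom_line(aes(y = .data$p_hat), color = "steelblue") +
    scale_x_continuous(breaks = seq(0, 24, 4),
                       labels = sprintf("%02d:00", seq(0, 24, 4))) +
    labs(x = "local time", y = "P(sensor active)",
         title = "Sensor Profile",
         subtitle = "per-bin activation probability with confidence band") +
    coord_cartesian(ylim = c(0, 1)) +
    theme_minimal()
}

#' Holm--Bonferroni adjustment of p-values
#'
#' Step-down family-wise error rate control: the i-th smallest p-value is
#' multiplied by (m - i + 1), a running maximum enforces monotonicity, and
#' values are capped at 1; results are returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' holm_bonferroni(c(0.04, 0.01, 0.02))
holm_bonferroni <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "holm")
}

two_proportion_test <- function(a_pos, a_tot, b_pos, b_tot) {
  tab <- matrix(c(a_pos, a_tot - a_pos, b_pos, b_tot - b_pos),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0)) return(NA_real_)
  # degenerate margins (all positive or all negative in both groups)
  if (any(colSums(tab) == 0)) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
}

#' Compare two periods' Sensor Profiles bin by bin
#'
#' For every time bin, tests equality of the two groups' activation
#' probabilities on the 2x2 table of positive/negative days (chi-square
#' without continuity correction; Fisher's exact test when any expected
#' cell is below 5). Raw p-values are Holm-adjusted across all bins to
#' control the family-wise error rate.
#'
#' @param traces_a,traces_b `day_traces` for the two periods (same bin
#'   structure).
#' @param alpha Significance level applied to adjusted p-values.
#' @return Tibble of class `profile_comparison`: `bin`, `p_hat_a`,
#'   `p_hat_b`, `raw_p`, `adjusted_p`, `significant`.
#' @export
compare_profiles <- function(traces_a, traces_b, alpha = 0.05) {
  if (nrow(traces_a) == 0 || nrow(traces_b) == 0) {
    abort("both groups must contain at least one day.")
  }
  pa <- estimate_profile(traces_a)
  pb <- estimate_profile(traces_b)
  if (!identical(pa$bin, pb$bin)) abort("groups must share the bin structure.")
  raw <- map_dbl(seq_len(nrow(pa)), function(j) {
    two_proportion_test(pa$n_pos[j], pa$n_total[j], pb$n_pos[j], pb$n_total[j])
  })
  testable <- !is.na(raw)
  adj <- rep(NA_real_, length(raw))
  adj[testable] <- holm_bonferroni(raw[testable])
  out <- tibble(
    bin = pa$bin,
    p_hat_a = pa$p_hat,
    p_hat_b = pb$p_hat,
    raw_p = raw,
    adjusted_p = adj,
    significant = !is.na(adj) & adj < alpha
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("profile_comparison", class(out))
  out
}
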