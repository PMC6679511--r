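default_epsilon <- function(prototype) {
  n <- max(prototype$n_total, na.rm = TRUE)
  eps <- max(1 / (2 * n), 0.005)
  if (eps >= 0.5) {
    abort("prototype sample size too small for the automatic clip bound; pass `epsilon` explicitly.")
  }
  eps
}

#' Novelty Score of day traces against a reference profile
#'
#' The Novelty Score of a day is the negative Bernoulli log-likelihood of
#' its trace under the reference Sensor Profile, summing over time bins
#' (bins are treated as conditionally independent):
#' `NS = -sum_j [x_j log theta_j + (1 - x_j) log(1 - theta_j)]`.
#' Profile probabilities are clipped into `[epsilon, 1 - epsilon]` so that
#' a day disagreeing with a degenerate bin estimate (0 or 1) yields a
#' large but finite score. By default `epsilon = 1 / (2 N)` with `N` the
#' profile's day count, floored at 0.005 -- a pseudo-count-like
#' regularization. `NA` bins in a trace are skipped.
#'
#' @param traces A `day_traces` tibble (one or more days).
#' @param prototype A [estimate_profile()] result with matching bins.
#' @param epsilon Clip bound in (0, 0.5), or `NULL` for the default.
#' @return Tibble `date`, `ns` (non-negative novelty score per day).
#' @export
novelty_score <- function(traces, prototype, epsilon = NULL) {
  m <- trace_matrix(traces)
  if (!identical(colnames(m), prototype$bin)) {
    abort("trace bins do not match the prototype's bin structure.")
  }
  epsilon <- epsilon %||% default_epsilon(prototype)
  if (epsilon <= 0 || epsilon >= 0.5) abort("`epsilon` must lie in (0, 0.5).")
  theta <- pmin(pmax(prototype$p_hat, epsilon), 1 - epsilon)
  ll <- sweep(m, 2, log(theta), `*`) + sweep(1 - m, 2, log(1 - theta), `*`)
  tibble(date = traces$date, ns = unname(-rowSums(ll, na.rm = TRUE)))
}

#' Label novelty scores with the interquartile-range rule
#'
#' The outlier threshold is `Q75 + 1.5 * (Q75 - Q25)` with
#' linear-interpolation percentiles; a day is an inlier when its score is
#' strictly below the threshold, an outlier otherwise. When all scores are
#' equal the IQR is zero, the threshold equals the common score and the
#' strict inequality labels every day an outlier; set
#' `guard_zero_iqr = TRUE` to require a positive IQR before flagging
#' anything.
#'
#' @param scores Numeric novelty scores, or a tibble from
#'   [novelty_score()] (at least 4 scores).
#' @param guard_zero_iqr If `TRUE`, a zero IQR flags nothing.
#' @return An object of class `novelty_result`: list with `scores` (tibble
#'   `date` if available, `ns`, `outlier`), `threshold`, `q25`, `q75`.
#' @export
#' @examples
#' iqr_outlier_threshold(c(1:8, 100))$threshold
iqr_outlier_threshold <- function(scores, guard_zero_iqr = FALSE) {
  if (is.data.frame(scores)) {
    ns <- scores$ns
    dates <- scores$date
  } else {
    ns <- as.numeric(scores)
    dates <- NULL
  }
  if (length(ns) < 4) abort("at least 4 scores are required.")
  q <- unname(quantile(ns, c(0.25, 0.75), type = 7))
  thr <- q[2] + 1.5 * (q[2] - q[1])
  outlier <- ns >= thr
  if (guard_zero_iqr && (q[2] - q[1]) == 0) outlier <- rep(FALSE, length(ns))
  tab <- tibble(ns = ns, outlier = outlier)
  if (!is.null(dates)) tab <- mutate(tab, date = dates, .before = 1)
  structure(list(scores = tab, threshold = thr, q25 = q[1], q75 = q[2]),
            class = "novelty_result")
}

#' Score traces against a prototype and flag deviant days
#'
#' Convenience composition of [novelty_score()] and
#' [iqr_outlier_threshold()].
#'
#' @inheritParams novelty_score
#' @inheritParams iqr_outlier_threshold
#' @return A `novelty_result`.
#' @export
detect_novelty <- function(traces, prototype, epsilon = NULL,
                           guard_zero_iqr = FALSE) {
  iqr_outlier_threshold(novelty_score(traces, prototype, epsilon),
                        guard_zero_iqr = guard_zero_iqr)
}

#' @export
print.novelty_result <- function(x, ...) {
  cat(sprintf("Novelty detection: threshold %.3f (Q25 %.3f, Q75 %.3f); %d/%d outlier day(s)\n",
              x$threshold, x$q25, x$q75, sum(x$scores$outlier), nrow(x$scores)))
  invisible(x)
}

#' @export
glance.novelty_result <- function(x, ...) {
  tibble(n_days = nrow(x$scores), n_outliers = sum(x$scores$outlier),
         threshold = x$threshold, q25 = x$q25, q75 = x$q75)
}

#' @export
autoplot.novelty_result <- function(object, bins = 30, ...) {
  ggplot(object$scores, aes(x = .data$ns)) +
    geom_histogram(bins = bins, fill = "steelblue", color = "white") +
    geom_vline(xintercept = object$threshold, color = "red",
               linetype = "dashed") +
    labs(x = "Novelty Score", y = "days",
         title = "Novelty Score distribution",
         subtitle = "dashed line: IQR outlier threshold") +
    theme_minimal()
}
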