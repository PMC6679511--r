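#' Canonical bin labels for a day
#'
#' Labels are the local clock time at which each bin starts, `"HH:MM"`.
#' A day is divided into `1440 / bin_width` canonical bins; on daylight-saving
#' transition days the actually observed bins are mapped back onto these
#' labels (see [bin_day_trace()]).
#'
#' @param bin_width Bin width in minutes; must divide 1440.
#' @return Character vector of `1440 / bin_width` labels.
#' @export
#' @examples
#' head(bin_labels(30))
bin_labels <- function(bin_width) {
  check_bin_width(bin_width)
  mins <- seq(0L, 1439L, by = as.integer(bin_width))
  sprintf("%02d:%02d", mins %/% 60L, mins %% 60L)
}

check_bin_width <- function(bin_width) {
  if (length(bin_width) != 1 || is.na(bin_width) || bin_width <= 0 ||
      1440 %% bin_width != 0) {
    abort("`bin_width` must be a positive number of minutes dividing 1440.")
  }
  invisible(bin_width)
}

#' Construct a day-trace table
#'
#' A day-trace table holds one row per day and one 0/1 column per time bin
#' (named by local clock start time, see [bin_labels()]), plus a `date`
#' column. `NA` entries mark bins that do not exist on that local day
#' (spring-forward daylight-saving gaps).
#'
#' @param dates Vector of `Date`s, one per row of `mat`.
#' @param mat Numeric matrix of 0/1 (or `NA`) activations, days by bins.
#' @param bin_width Bin width in minutes.
#' @param timezone IANA timezone name the bins refer to.
#' @return A tibble of class `day_traces`.
#' @export
new_day_traces <- function(dates, mat, bin_width = 30, timezone = "UTC") {
  check_bin_width(bin_width)
  labs <- bin_labels(bin_width)
  mat <- as.matrix(mat)
  if (ncol(mat) != length(labs)) {
    abort(sprintf("trace matrix has %d columns, expected %d for bin_width = %s",
                  ncol(mat), length(labs), bin_width))
  }
  bad <- !(is.na(mat) | mat == 0 | mat == 1)
  if (any(bad)) abort("trace entries must be 0, 1 or NA")
  colnames(mat) <- labs
  out <- bind_cols(tibble(date = as.Date(dates)), as_tibble(mat))
  attr(out, "bin_width") <- bin_width
  attr(out, "timezone") <- timezone
  class(out) <- c("day_traces", class(out))
  out
}

#' Extract the activation matrix from a day-trace table
#'
#' @param traces A `day_traces` tibble.
#' @return Numeric matrix (days by bins) with dates as row names.
#' @export
trace_matrix <- function(traces) {
  stopifnot(is.data.frame(traces), "date" %in% names(traces))
  labs <- setdiff(names(traces), "date")
  m <- as.matrix(as.data.frame(traces)[labs])
  rownames(m) <- as.character(traces$date)
  storage.mode(m) <- "double"
  m
}

trace_bin_width <- function(traces) {
  bw <- attr(traces, "bin_width")
  if (is.null(bw)) bw <- 1440 / (ncol(traces) - 1)
  bw
}

trace_timezone <- function(traces) {
  attr(traces, "timezone") %||% "UTC"
}
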