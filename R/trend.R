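#' Specify the rolling trend-model design
#'
#' The daily-count model is a log-link Poisson regression fitted on a
#' rolling window of the last `window` daily counts, with four candidate
#' factors: a baseline (intercept), a linear trend over the whole window
#' (scaled to \[0, 1\], so its coefficient is the log fold-change across the
#' window), an abrupt-trend indicator covering the most recent `abrupt`
#' days, and an intermediate-period indicator covering the `intermediate`
#' days just before the abrupt span (which absorbs a past step change
#' without inflating the baseline).
#'
#' @param window Window length W in days (default 30).
#' @param abrupt Length A of the abrupt span (default 5).
#' @param intermediate Length I of the intermediate span (default 10);
#'   `abrupt + intermediate < window` is required.
#' @param alpha Significance level for factor retention (default 0.05).
#' @param level Coverage of the central interval used to label unexplained
#'   days (default 0.95).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(window = 30, abrupt = 5, intermediate = 10,
                        alpha = 0.05, level = 0.95) {
  if (abrupt + intermediate >= window) {
    abort("`abrupt + intermediate` must be smaller than `window`.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1).")
  structure(list(window = as.integer(window), abrupt = as.integer(abrupt),
                 intermediate = as.integer(intermediate),
                 alpha = alpha, level = level),
            class = "design_spec")
}

#' Build the rolling-window design matrix
#'
#' Rows are window days `d = 1..W` in time order (`d = W` is the most
#' recent). Columns: `bias = 1`; `linear = (d - 1) / (W - 1)`;
#' `abrupt = 1` on the last A days; `intermediate = 1` on the I days
#' preceding the abrupt span.
#'
#' @param spec A [design_spec()].
#' @return Numeric matrix `W x 4` with columns
#'   `bias`, `linear`, `intermediate`, `abrupt`.
#' @export
#' @examples
#' colSums(build_design(design_spec()))
build_design <- function(spec = design_spec()) {
  W <- spec$window; A <- spec$abrupt; I <- spec$intermediate
  d <- seq_len(W)
  cbind(
    bias = rep(1, W),
    linear = if (W > 1) (d - 1) / (W - 1) else rep(0, W),
    intermediate = as.numeric(d > W - A - I & d <= W - A),
    abrupt = as.numeric(d > W - A)
  )
}

#' Fit the Poisson count model on one window
#'
#' Maximum-likelihood log-link Poisson regression (iteratively reweighted
#' least squares) of the window's counts on the given design columns, with
#' Wald standard errors and p-values. Missing counts (`NA`) are dropped
#' from the likelihood; their design rows are dropped pairwise. Factors
#' that are not estimable on the window (e.g., an indicator spanning only
#' zero counts, which drives its coefficient to minus infinity) are
#' excluded and recorded in `dropped`.
#'
#' @param counts Non-negative integer counts, one per design row; `NA`
#'   allowed.
#' @param design Design matrix from [build_design()] (or any subset of its
#'   columns including `bias`).
#' @return An object of class `poisson_trend_fit`: a list with
#'   `coefficients`, `se`, `p_values` (non-bias factors), `retained`,
#'   `dropped`, `mu` (fitted mean for every design row), `converged`,
#'   `deviance`, `n_used`.
#' @export
fit_poisson_glm <- function(counts, design) {
  design <- as.matrix(design)
  if (length(counts) != nrow(design)) {
    abort("`counts` length must equal the number of design rows.")
  }
  if (!"bias" %in% colnames(design)) abort("design must contain a `bias` column.")
  use <- !is.na(counts)
  factors <- colnames(design)
  dropped <- character(0)
  repeat {
    cols <- setdiff(factors, dropped)
    X <- design[use, cols, drop = FALSE]
    y <- counts[use]
    dat <- as.data.frame(X)
    dat$.y <- y
    fml <- stats::reformulate(sprintf("`%s`", cols), response = ".y", intercept = FALSE)
    fit <- suppressWarnings(
      glm(fml, data = dat, family = poisson(),
          control = glm.control(epsilon = 1e-12, maxit = 100))
    )
    beta <- coef(fit)
    names(beta) <- cols
    bad <- cols[is.na(beta) | abs(beta) > 20]
    bad <- setdiff(bad, "bias")
    if (length(bad) == 0) break
    dropped <- c(dropped, bad)
  }
  sm <- suppressWarnings(summary(fit)$coefficients)
  rownames(sm) <- cols
  se <- sm[, "Std. Error"]
  pv <- sm[, "Pr(>|z|)"]
  mu <- as.numeric(exp(design[, cols, drop = FALSE] %*% beta))
  structure(list(
    coefficients = beta,
    se = setNames(as.numeric(se), cols),
    p_values = setNames(as.numeric(pv[setdiff(cols, "bias")]), setdiff(cols, "bias")),
    retained = cols,
    dropped = dropped,
    mu = mu,
    converged = isTRUE(fit$converged),
    deviance = as.numeric(fit$deviance),
    n_used = sum(use)
  ), class = "poisson_trend_fit")
}

#' Retain only statistically significant factors
#'
#' Realizes the rule that only statistically significant factors (Wald
#' p < `alpha`) are retained and used for model fitting; the bias is never
#' removed. Two realizations are provided:
#'
#' * `"screen"` (default): a single screening pass -- fit the full model,
#'   drop every non-bias factor with p >= `alpha`, refit once with the
#'   survivors. Each factor is tested exactly once, so under a constant-rate
#'   null each is falsely retained at rate ~ `alpha`.
#' * `"stepwise"`: classical backward elimination -- iteratively refit after
#'   removing the non-bias factor with the largest p >= `alpha` until all
#'   retained factors are significant. Factors get several testing chances,
#'   which mildly inflates the null retention rate above `alpha`.
#'
#' @inheritParams fit_poisson_glm
#' @param spec A [design_spec()] providing `alpha`.
#' @param method `"screen"` or `"stepwise"` (see above).
#' @return A `poisson_trend_fit` for the selected model.
#' @export
backward_select <- function(counts, design, spec = design_spec(),
                            method = c("screen", "stepwise")) {
  method <- match.arg(method)
  design <- as.matrix(design)
  cols <- colnames(design)
  if (method == "screen") {
    fit <- fit_poisson_glm(counts, design)
    pv <- fit$p_values[!is.na(fit$p_values)]
    drop <- names(pv)[pv >= spec$alpha]
    keep <- setdiff(fit$retained, drop)
    if (setequal(keep, fit$retained)) return(fit)
    return(fit_poisson_glm(counts, design[, keep, drop = FALSE]))
  }
  repeat {
    fit <- fit_poisson_glm(counts, design[, cols, drop = FALSE])
    pv <- fit$p_values
    pv <- pv[!is.na(pv)]
    if (length(pv) == 0 || max(pv) < spec$alpha) return(fit)
    worst <- names(pv)[which.max(pv)]
    cols <- setdiff(fit$retained, worst)
  }
}

#' @export
tidy.poisson_trend_fit <- function(x, ...) {
  tibble(
    term = x$retained,
    estimate = as.numeric(x$coefficients[x$retained]),
    std_error = as.numeric(x$se[x$retained]),
    p_value = as.numeric(ifelse(x$retained == "bias", NA,
                                x$p_values[x$retained]))
  )
}

#' @export
glance.poisson_trend_fit <- function(x, ...) {
  tibble(deviance = x$deviance, converged = x$converged, n_used = x$n_used,
         n_factors = length(x$retained))
}

#' Equal-tailed central interval of a Poisson distribution
#'
#' Integer bounds of the region containing at least `level` of the
#' probability mass: `lo` is the smallest count with CDF >= (1 - level)/2
#' and `hi` the smallest count with CDF >= 1 - (1 - level)/2. Observed
#' counts outside `[lo, hi]` are labeled unexplained by the fitted model.
#'
#' @param mu Positive fitted mean(s).
#' @param level Coverage level (default 0.95).
#' @return Tibble with columns `mu`, `lo`, `hi`, one row per `mu`.
#' @export
#' @examples
#' poisson_central_interval(4)
poisson_central_interval <- function(mu, level = 0.95) {
  if (any(mu <= 0)) abort("`mu` must be positive.")
  a <- (1 - level) / 2
  tibble(mu = mu,
         lo = qpois(a, mu),
         hi = qpois(1 - a, mu))
}

#' Multiplicative effect of each retained factor
#'
#' On the log link, a factor's marginal effect is multiplicative: a unit
#' increment multiplies the expected count by `exp(beta)`. The bias row is
#' the baseline expected daily count.
#'
#' @param fit A `poisson_trend_fit`.
#' @return Tibble `term`, `multiplier`, `percent_change` where
#'   `percent_change = 100 * (exp(beta) - 1)`.
#' @export
factor_effects <- function(fit) {
  stopifnot(inherits(fit, "poisson_trend_fit"))
  if (!fit$converged) warn("fit did not converge; effects may be unreliable.")
  b <- fit$coefficients[fit$retained]
  tibble(term = fit$retained,
         multiplier = as.numeric(exp(b)),
         percent_change = 100 * (as.numeric(exp(b)) - 1))
}

#' Cosine similarity of two non-negative series
#'
#' `dot(a, b) / (||a|| * ||b||)`, used to compare count series between
#' periods or subjects, and day traces to each other. Zero-vector
#' convention: two zero vectors are maximally similar (1); a zero vector
#' against a non-zero one has similarity 0.
#'
#' @param a,b Equal-length numeric vectors.
#' @return Similarity score in \[0, 1\] for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
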