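# shared fixture builders; everything is generated in code

make_events <- function(times, event, sensor_id = "bed-1", sensor_type = "bed",
                        burst_id = NA_character_) {
  tibble::tibble(
    timestamp_utc = as.POSIXct(times, tz = "UTC"),
    sensor_id = sensor_id,
    sensor_type = sensor_type,
    event = event,
    burst_id = burst_id
  )
}

single_mode <- function(p, n_bins = 48, name = "m", weight = 1) {
  mode_spec(name, rep(p, n_bins), weight)
}

# independent Poisson log-likelihood maximizer (BFGS on the hand-written
# objective); the oracle against which the IRLS fit is checked
oracle_poisson_fit <- function(y, X) {
  nll <- function(b) {
    eta <- as.numeric(X %*% b)
    sum(exp(eta)) - sum(y * eta)
  }
  grad <- function(b) {
    eta <- as.numeric(X %*% b)
    as.numeric(t(X) %*% (exp(eta) - y))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 1000))
  stats::setNames(fit$par, colnames(X))
}

# manual stepwise Holm computation, kept independent of the implementation
oracle_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# mixed trace set with fixed composition (the IQR rule needs the deviant
# share safely below its 25% breakdown point)
make_mixed_traces <- function(n_dominant = 45, n_minor = 10, n_deviant = 2,
                              seed = 1) {
  modes <- well_separated_modes()
  dom <- sample_day_traces(list(mode_spec("night-only", modes[[1]]$bin_probabilities, 1)),
                           n_dominant, seed = seed)
  minor <- sample_day_traces(list(mode_spec("night-plus-nap", modes[[2]]$bin_probabilities, 1)),
                             n_minor, seed = seed + 1)
  dev <- sample_day_traces(list(mode_spec("deviant", deviant_daytime_probs(), 1)),
                           n_deviant, seed = seed + 2)
  mat <- rbind(trace_matrix(dom$traces), trace_matrix(minor$traces),
               trace_matrix(dev$traces))
  n <- nrow(mat)
  truth <- rep(c("night-only", "night-plus-nap", "deviant"),
               c(n_dominant, n_minor, n_deviant))
  list(traces = new_day_traces(as.Date("2024-01-01") + seq_len(n) - 1, mat),
       truth = truth)
}

# central Poisson interval by direct pmf summation
oracle_central_interval <- function(mu, level = 0.95) {
  a <- (1 - level) / 2
  kmax <- stats::qpois(1 - 1e-12, mu) + 10
  cdf <- cumsum(stats::dpois(0:kmax, mu))
  c(lo = which(cdf >= a)[1] - 1L, hi = which(cdf >= 1 - a)[1] - 1L)
}
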