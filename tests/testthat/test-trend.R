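test_that("the design matrix follows the index rules", {
  d <- build_design(design_spec(window = 30, abrupt = 5, intermediate = 10))
  expect_equal(unname(d[30, ]), c(1, 1, 0, 1))
  expect_equal(unname(d[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(colSums(d)), c(30, 15, 10, 5))
  expect_error(design_spec(window = 14, abrupt = 5, intermediate = 10), "smaller")
})

test_that("closed-form fits recover groupwise means", {
  d <- build_design(design_spec())
  f <- fit_poisson_glm(rep(4L, 30), d[, "bias", drop = FALSE])
  expect_equal(unname(f$coefficients["bias"]), log(4), tolerance = 1e-8)
  expect_equal(f$mu, rep(4, 30), tolerance = 1e-8)

  # saturated indicator design: bias = log lower mean, abrupt = log ratio
  spec4 <- design_spec(window = 30, abrupt = 4, intermediate = 10)
  d4 <- build_design(spec4)[, c("bias", "abrupt")]
  y <- c(rep(2L, 26), rep(4L, 4))
  f2 <- fit_poisson_glm(y, d4)
  expect_equal(unname(f2$coefficients), c(log(2), log(2)), tolerance = 1e-8)
})

test_that("IRLS coefficients agree with an independent likelihood maximizer", {
  d <- build_design(design_spec())
  withr::with_seed(31, {
    for (i in 1:25) {
      beta <- c(log(runif(1, 2, 8)), rnorm(3, 0, 0.3))
      y <- rpois(30, exp(as.numeric(d %*% beta)))
      fit <- fit_poisson_glm(y, d)
      ref <- oracle_poisson_fit(y, d)
      expect_lt(max(abs(fit$coefficients - ref[names(fit$coefficients)])), 1e-6)
    }
  })
})

test_that("missing days are dropped pairwise from the likelihood", {
  d <- build_design(design_spec())
  y <- rep(4L, 30)
  y[c(3, 17)] <- NA
  f <- fit_poisson_glm(y, d[, "bias", drop = FALSE])
  expect_equal(f$n_used, 28)
  expect_equal(unname(f$coefficients["bias"]), log(4), tolerance = 1e-8)
})

test_that("non-estimable factors are excluded and recorded", {
  d <- build_design(design_spec())
  y <- c(rep(4L, 25), rep(0L, 5)) # abrupt span all zero -> -Inf coefficient
  f <- fit_poisson_glm(y, d)
  expect_true("abrupt" %in% f$dropped)
  expect_false("abrupt" %in% f$retained)
})

test_that("factor selection keeps only significant factors", {
  spec <- design_spec()
  d <- build_design(spec)
  for (m in c("screen", "stepwise")) {
    f <- backward_select(rep(4L, 30), d, spec, method = m)
    expect_equal(f$retained, "bias")
  }
  # alpha -> 1 retains the full model (non-degenerate data, so p < 1)
  y_var <- withr::with_seed(8, rpois(30, 5))
  f_all <- backward_select(y_var, d, design_spec(alpha = 1 - 1e-12),
                           method = "stepwise")
  expect_setequal(f_all$retained, c("bias", "linear", "intermediate", "abrupt"))
  # every retained non-bias factor is significant at alpha
  withr::with_seed(5, {
    for (i in 1:20) {
      y <- rpois(30, 6)
      for (m in c("screen", "stepwise")) {
        f <- backward_select(y, d, spec, method = m)
        pv <- f$p_values[setdiff(f$retained, "bias")]
        if (m == "stepwise" && length(pv) > 0) expect_true(all(pv < spec$alpha))
      }
    }
  })
})

test_that("an injected step is detected mostly as an abrupt factor", {
  spec <- design_spec()
  d <- build_design(spec)
  hit_a <- 0; hit_l <- 0
  for (s in 1:100) {
    sc <- count_scenario(30, 20, abrupt_start_day = 26,
                         abrupt_log_effect = log(2), seed = s)
    y <- simulate_daily_counts(sc)$counts$count
    f <- backward_select(y, d, spec)
    hit_a <- hit_a + ("abrupt" %in% f$retained)
    hit_l <- hit_l + ("linear" %in% f$retained)
  }
  expect_gt(hit_a / 100, 0.5)
  expect_lt(hit_l / 100, 0.5)
})

test_that("central Poisson intervals match direct pmf summation", {
  ci <- poisson_central_interval(4)
  expect_equal(c(ci$lo, ci$hi), c(1, 8))
  ci2 <- poisson_central_interval(0.01)
  expect_equal(c(ci2$lo, ci2$hi), c(0, 0))
  withr::with_seed(17, {
    mus <- exp(runif(200, log(0.05), log(80)))
    got <- poisson_central_interval(mus)
    for (i in seq_along(mus)) {
      ref <- oracle_central_interval(mus[i])
      expect_equal(c(got$lo[i], got$hi[i]), unname(ref))
      mass <- ppois(got$hi[i], mus[i]) - ppois(got$lo[i] - 1, mus[i])
      expect_gte(mass, 0.95)
    }
  })
})

test_that("factor effects are multiplicative on the response scale", {
  f <- structure(list(coefficients = c(bias = log(4), abrupt = log(2),
                                       linear = 0, intermediate = -log(4)),
                      retained = c("bias", "abrupt", "linear", "intermediate"),
                      converged = TRUE),
                 class = "poisson_trend_fit")
  eff <- factor_effects(f)
  expect_equal(eff$multiplier[eff$term == "abrupt"], 2)
  expect_equal(eff$percent_change[eff$term == "abrupt"], 100)
  expect_equal(eff$percent_change[eff$term == "linear"], 0)
  expect_equal(eff$multiplier[eff$term == "intermediate"], 0.25)
  expect_equal(eff$percent_change[eff$term == "intermediate"], -75)
})

test_that("cosine similarity follows the closed form and zero conventions", {
  expect_equal(cosine_similarity(c(2, 3, 1), c(2, 3, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0, 0), c(0, 0)), 1)
  expect_equal(cosine_similarity(c(0, 0), c(1, 0)), 0)
  expect_error(cosine_similarity(1:3, 1:2), "equal length")
})

test_that("fit summaries tidy into term tables", {
  d <- build_design(design_spec())
  f <- fit_poisson_glm(rep(5L, 30), d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std_error", "p_value"))
  expect_equal(nrow(td), 4)
  g <- glance(f)
  expect_true(g$converged)
  expect_equal(g$n_used, 30)
})
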