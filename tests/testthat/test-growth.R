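test_that("growth data table has study-scale dimensions and excludes non-responses", {
  coh <- small_default_cohort(n_per_group = 4, rng_seed = 1)
  fit <- suppressWarnings(cpca(coh, n_components = 3))
  curves <- response_curves(fit)
  d <- growth_data(curves, coh$covariates, fit$component_labels[2])
  expect_true(all(d$response_class != "non-response"))
  # at most subjects x 4 events x 6 lags rows (absent event types drop out)
  expect_lte(nrow(d), 8 * 4 * 6)
  expect_equal(sort(unique(d$time)), c(-7.5, -4.5, -1.5, 1.5, 4.5, 7.5))
  # at the full study scale the same arithmetic gives 116 x 4 x 6 = 2784 rows
  expect_equal(116 * 4 * 6, 2784)
})

test_that("known quadratic effect is recovered with near-nominal CI coverage", {
  truth <- c(time = 0.05, time2 = 0.04)
  hits <- 0
  for (r in 1:40) {
    d <- simulate_growth_data(30, truth, rng_seed = 100 + r)
    f <- suppressMessages(fit_growth_model(d, terms = c("time", "time2")))
    co <- f$coefficients[f$coefficients$term == "time2", ]
    hits <- hits + (abs(co$estimate - 0.04) <= stats::qt(0.975, co$df) * co$se)
  }
  expect_gte(hits, 34)  # ~95% nominal over 40 replicates
})

test_that("permuted group labels give null group effects", {
  set.seed(77)
  truth <- c(time = 0.05, time2 = -0.03)
  zs <- vapply(1:10, function(r) {
    d <- simulate_growth_data(40, truth, rng_seed = 200 + r)
    # permute group within the subject table
    subj <- unique(d$subject)
    newg <- setNames(sample(rep(0:1, length.out = length(subj))), subj)
    d$group_case <- unname(newg[d$subject])
    f <- suppressMessages(fit_growth_model(d, terms = c("time", "time2",
                                                        "time2:group_case")))
    co <- f$coefficients[grepl("time2", f$coefficients$term) &
                           grepl("group_case", f$coefficients$term), ]
    co$t
  }, 0)
  expect_lt(abs(mean(zs)), 1)
  expect_gt(mean(abs(zs) < 3), 0.8)
})

test_that("zero random variance reduces the mixed model to pooled OLS", {
  d <- simulate_growth_data(30, c(time = 0.05, time2 = -0.02),
                            random_intercept_sd = 0, rng_seed = 5)
  mm <- suppressMessages(fit_growth_model(d, terms = c("time", "time2"),
                                          method = "ML"))
  expect_true(lme4::isSingular(mm$model))
  ols <- fit_growth_model(d, terms = c("time", "time2"), random = "none")
  expect_equal(mm$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("containment df separate within- from between-subject terms", {
  d <- simulate_growth_data(30, c(time = 0.05), rng_seed = 6)
  f <- suppressMessages(fit_growth_model(d, terms = "time"))
  co <- f$coefficients
  df_time <- co$df[co$term == "time"]
  df_group <- co$df[co$term == "group_case"]
  expect_gt(df_time, 500)   # within stratum: ~ n_obs - n_subj
  expect_lt(df_group, 30)   # between stratum: ~ n_subj - p - 1
})

test_that("selection ladder hierarchy is validated", {
  bad <- list(list(term = "time2:group_case", requires = "time2"),
              list(term = "time2", requires = "time"),
              list(term = "time", requires = character(0)))
  d <- simulate_growth_data(10, c(time = 0.05), rng_seed = 7)
  expect_error(select_growth_model(d, ladder = bad), "invalid ladder")
  expect_error(select_growth_model(d, ladder = list()), "empty")
})

test_that("selection recovers a cubic + group interaction and stays quiet under noise", {
  truth <- c(time = 0.05, time2 = -0.03, time3 = 0.004,
             "time2:group_case" = 0.02)
  recovered <- 0
  for (r in 1:8) {
    d <- simulate_growth_data(40, truth, rng_seed = 300 + r)
    s <- suppressWarnings(suppressMessages(select_growth_model(d)))
    recovered <- recovered +
      (all(c("time", "time2", "time3", "time2:group_case") %in% s$terms) &&
         !any(c("time4", "time5") %in% s$terms))
  }
  expect_gte(recovered, 7)
  # pure noise: only mandatory covariates retained at ~alpha rate
  extra <- vapply(1:6, function(r) {
    d0 <- simulate_growth_data(30, c(time = 0), residual_sd = 1,
                               rng_seed = 400 + r)
    s0 <- suppressWarnings(suppressMessages(select_growth_model(d0)))
    length(s0$terms)
  }, 0)
  expect_lte(mean(extra), 0.5)
  # selection trace is deterministic given data and ladder
  d <- simulate_growth_data(30, truth, rng_seed = 999)
  s1 <- suppressWarnings(suppressMessages(select_growth_model(d)))
  s2 <- suppressWarnings(suppressMessages(select_growth_model(d)))
  expect_identical(s1$trace, s2$trace)
  expect_identical(s1$terms, s2$terms)
})

test_that("random time slope is detected when planted and dropped when singular", {
  d <- simulate_growth_data(50, c(time = 0.06, time2 = -0.02),
                            random_slope_sd = 0.08, rng_seed = 8)
  s <- suppressWarnings(suppressMessages(select_growth_model(d)))
  expect_equal(s$random, "slope")
  expect_false(s$fit$singular_slope)
  # force a singular slope fit directly (small sample, no true slope variance)
  d0 <- simulate_growth_data(12, c(time = 0.02), random_slope_sd = 0,
                             residual_sd = 1, rng_seed = 1)
  f <- suppressMessages(fit_growth_model(d0, terms = "time", random = "slope"))
  expect_true(f$singular_slope)
  expect_equal(f$random, "intercept")
})
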