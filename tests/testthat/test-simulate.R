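test_that("noiseless single-trial run equals the outer product of curve and map", {
  model <- noiseless_model(n_regions = 12)
  s <- generate_event_schedule(n_trials = 1, isi_bounds = c(0.5, 24.5),
                               run_duration = 30, rng_seed = 1)
  b <- generate_subject_bold(s, model, rng_seed = 1)
  expect_equal(nrow(b$data), 10)
  # onset 0: curve values occupy volumes 0..5 exactly
  placed <- matrix(0, 10, 1)
  placed[1:6, 1] <- model$response_curves[1, trial_event_type(s)[1], ]
  expect_equal(b$data, placed %*% model$spatial_maps, tolerance = 1e-12)
})

test_that("volume count is run duration over TR", {
  model <- noiseless_model()
  s <- generate_event_schedule(rng_seed = 2)
  b <- generate_subject_bold(s, model, rng_seed = 2)
  expect_equal(nrow(b$data), 210)
})

test_that("pure-noise lag-1 autocorrelation converges to the AR coefficient", {
  lag <- (1:6 - 0.5) * 3
  curves <- array(0, c(1, 6, 6), dimnames = list(NULL, event_types(), NULL))
  model <- planted_model(orthonormal_maps(1, 3, rng_seed = 1), curves,
                         noise_ar = 0.4, noise_sd = 1, subject_amplitude_sd = 0)
  s <- generate_event_schedule(n_trials = 1, isi_bounds = c(0.5, 31000),
                               run_duration = 31000, rng_seed = 3)
  b <- generate_subject_bold(s, model, rng_seed = 3)
  expect_gte(nrow(b$data), 1e4)
  ac <- apply(b$data, 2, function(x) stats::acf(x, plot = FALSE)$acf[2])
  expect_true(all(abs(ac - 0.4) < 0.05))
})

test_that("component/region dimension mismatches are rejected", {
  model <- noiseless_model(n_regions = 12)
  s <- generate_event_schedule(n_trials = 1, isi_bounds = c(0.5, 24.5),
                               run_duration = 30, rng_seed = 1)
  expect_error(generate_subject_bold(s, model, amplitudes = c(1, 2)),
               "amplitudes")
  expect_error(planted_model(2 * model$spatial_maps, model$response_curves),
               "orthonormal")
  expect_error(planted_model(model$spatial_maps, model$response_curves,
                             noise_ar = 1.2), "AR coefficient")
})

test_that("cohort generation is a pure function of config and seed", {
  a <- small_default_cohort(n_per_group = 2, rng_seed = 5)
  b <- small_default_cohort(n_per_group = 2, rng_seed = 5)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$subjects[[3]]$bold$data, b$subjects[[3]]$bold$data)
  expect_identical(a$subjects[[2]]$events$onset, b$subjects[[2]]$events$onset)
  d <- small_default_cohort(n_per_group = 2, rng_seed = 6)
  expect_false(identical(a$subjects[[1]]$bold$data, d$subjects[[1]]$bold$data))
})

test_that("cohort bundles carry groups, covariates and ground truth", {
  coh <- small_default_cohort(n_per_group = 3, rng_seed = 4)
  expect_length(coh$subjects, 6)
  expect_equal(table(coh$covariates$group)[["case"]], 3)
  expect_true(all(coh$covariates$accuracy >= 0 & coh$covariates$accuracy <= 1))
  expect_true(all(coh$covariates$mean_framewise_displacement >= 0))
  expect_equal(dim(coh$ground_truth$amplitudes),
               c(6, nrow(coh$ground_truth$model$spatial_maps)))
  expect_error(generate_cohort(0, 5), "at least one")
})

test_that("case-group lag mask removes late positive response in planted curves", {
  model <- default_planted_model(n_regions = 40, n_cortical = 34, rng_seed = 2)
  k <- 6  # biphasic component: late lags masked for cases
  cc <- model_curve(model, k, "control")
  ca <- model_curve(model, k, "case")
  expect_true(all(ca[, 5:6] == 0))
  expect_true(any(cc[, 5:6] != 0))
})

test_that("structural maps are reproducible, cortical-only, and null when effect is 0", {
  model <- default_planted_model(n_regions = 60, n_cortical = 50, rng_seed = 2)
  m1 <- generate_structural_maps(model, truth_component = 3, effect_size = 1.5,
                                 rng_seed = 9)
  m2 <- generate_structural_maps(model, truth_component = 3, effect_size = 1.5,
                                 rng_seed = 9)
  expect_identical(m1$surface_area$value, m2$surface_area$value)
  expect_equal(nrow(m1$thickness), 50)
  m0 <- generate_structural_maps(model, truth_component = NA, effect_size = 0,
                                 rng_seed = 9)
  expect_identical(m0$thickness$value, m1$thickness$value)  # same smooth noise
  expect_false(identical(m0$surface_area$value, m1$surface_area$value))
})
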