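# minimal pseudoinverse helper for constructing design-orthogonal noise
MASS_ginv <- function(G) {
  sv <- svd(G)
  pos <- sv$d > max(dim(G)) * .Machine$double.eps * sv$d[1]
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

test_that("FIR projection splits the series into orthogonal parts", {
  s <- generate_event_schedule(n_trials = 20, run_duration = 300, rng_seed = 1)
  d <- build_fir_design(s, 100, 3, 18)
  set.seed(14)
  X <- matrix(rnorm(100 * 15), 100, 15)
  tv <- extract_task_variance(X, d, standardize = "zscore")
  Z <- tv$predicted + tv$residual
  expect_lt(max(abs(crossprod(d$G, tv$residual))), 1e-8)
  expect_lt(max(abs(sum(tv$predicted * tv$residual))), 1e-6)
  # standardization record allows exact reconstruction of Z
  expect_equal(Z, scale(X)[, ], tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(extract_task_variance(X[1:50, ], d), "volume mismatch")
})

test_that("series inside span(G) leave no residual; orthogonal series no prediction", {
  model <- noiseless_model(n_regions = 10)
  coh <- suppressWarnings(generate_cohort(1, 1, model,
                                          config = nonoverlap_config(), rng_seed = 2))
  sub <- coh$subjects[[1]]
  tv <- extract_task_variance(sub$bold, sub$design, standardize = "none")
  expect_lt(sqrt(sum(tv$residual^2)), 1e-8)
  # pure-noise series orthogonalized against the design
  X <- matrix(rnorm(nrow(sub$design$G) * 5), ncol = 5)
  X <- X - sub$design$G %*% (MASS_ginv(sub$design$G) %*% X)
  tv2 <- extract_task_variance(X, sub$design, standardize = "none")
  expect_lt(sqrt(sum(tv2$predicted^2)), 1e-8)
})

test_that("noiseless rank-1 data give exact loading recovery and full variance", {
  model <- noiseless_model(n_regions = 30)
  coh <- suppressWarnings(generate_cohort(3, 3, model,
                                          config = nonoverlap_config(), rng_seed = 3))
  fit <- suppressWarnings(cpca(coh, n_components = 1, standardize = "none",
                               global_threshold = 2))
  expect_equal(fit$variance_explained[1], 1, tolerance = 1e-9)
  expect_gt(abs(cosine_sim(fit$loadings[, 1], model$spatial_maps[1, ])), 0.999)
})

test_that("two orthogonal components at 2:1 amplitude split variance 0.8 / 0.2", {
  model <- two_component_model()
  coh <- suppressWarnings(generate_cohort(3, 3, model,
                                          config = nonoverlap_config(), rng_seed = 4))
  fit <- suppressWarnings(cpca(coh, n_components = 2, standardize = "none",
                               global_threshold = 2))
  expect_equal(fit$variance_explained[1:2], c(0.8, 0.2), tolerance = 1e-6)
})

test_that("solution is invariant to subject concatenation order up to sign", {
  coh <- small_default_cohort(n_per_group = 3, rng_seed = 5)
  fit1 <- suppressWarnings(cpca(coh, n_components = 3))
  coh2 <- coh
  perm <- c(4, 2, 6, 1, 3, 5)
  coh2$subjects <- coh$subjects[perm]
  coh2$covariates <- coh$covariates[perm, ]
  fit2 <- suppressWarnings(cpca(coh2, n_components = 3))
  expect_equal(abs(fit1$loadings), abs(fit2$loadings), tolerance = 1e-8,
               ignore_attr = TRUE)
  # deterministic sign convention makes them exactly equal
  expect_equal(fit1$loadings, fit2$loadings, tolerance = 1e-8)
})

test_that("stacked predicted matrices reconstruct from scores and loadings", {
  coh <- small_default_cohort(n_per_group = 2, rng_seed = 6)
  fit <- suppressWarnings(cpca(coh, n_components = 60))  # full region rank
  for (i in c(1, 4)) {
    recon <- fit$scores[[i]] %*% t(fit$loadings)
    expect_equal(unname(recon), unname(fit$predicted[[i]]), tolerance = 1e-8)
  }
})

test_that("scree elbow by distance-to-chord lands at six on the reference sequence", {
  ve <- c(.37, .08, .07, .05, .04, .03, .005, .004, .003, .002, .0015, .001)
  expect_equal(choose_n_components(ve)$retained, 6)
  expect_error(choose_n_components(c(.1, .5)), "non-increasing")
  # geometric decay: criterion returns a stable index; explicit override wins
  vg <- 0.5^(1:12); vg <- vg / sum(vg)
  k <- choose_n_components(vg)$retained
  expect_true(k >= 1 && k <= 12)
  coh <- small_default_cohort(n_per_group = 2, rng_seed = 7)
  fit <- suppressWarnings(cpca(coh, n_components = 4))
  expect_equal(fit$n_components, 4)
  expect_equal(nrow(summary(fit)$table), 4)
})

test_that("a same-sign component is flagged global and components re-indexed", {
  # constructed solution: uniform map + bipolar maps
  set.seed(31)
  u <- rep(1, 50) / sqrt(50)
  V <- qr.Q(qr(cbind(u, matrix(rnorm(100), 50, 2))))
  V[, 1] <- abs(V[, 1])
  expect_equal(identify_global_component(V, threshold = 0.9), 1L)
  expect_true(is.na(identify_global_component(V[, 2:3, drop = FALSE])))
  # end-to-end: drift-carrying planted model flags PC0 and relabels the rest
  model <- default_planted_model(n_regions = 60, n_cortical = 50, rng_seed = 2)
  coh <- suppressWarnings(generate_cohort(6, 6, model, rng_seed = 8))
  fit <- suppressWarnings(cpca(coh, n_components = 6))
  expect_false(is.na(fit$global_component))
  expect_equal(sort(fit$component_labels),
               sort(c("PC0", paste0("PC", 1:5))))
  expect_equal(fit$component_labels[fit$global_component], "PC0")
})
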