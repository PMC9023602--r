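make_curveset <- function(est, lag_times = (1:6 - 0.5) * 3) {
  structure(list(estimates = est, lag_times = lag_times,
                 event_types = dimnames(est)[[3]],
                 subject_ids = dimnames(est)[[1]],
                 component_labels = dimnames(est)[[2]]),
            class = "response_curve_set")
}

test_that("peak extraction follows the max-|.| convention with earliest-lag ties", {
  ev <- event_types(response_only = TRUE)
  est <- array(NA_real_, c(1, 1, 4, 6),
               dimnames = list("s1", "PC1", ev, paste0("lag", 0:5)))
  est[1, 1, 1, ] <- c(0.1, 0.5, 0.3, -0.2, -0.1, 0)
  est[1, 1, 2, ] <- c(0.1, 0.2, -0.6, 0.1, 0, 0)
  est[1, 1, 3, ] <- c(0.4, 0.1, 0.4, 0, 0, 0)     # tie -> earliest lag
  est[1, 1, 4, ] <- c(-0.3, 0.2, 0, 0, 0, 0.3)
  pk <- extract_peak_scores(make_curveset(est))
  get <- function(e) pk[pk$event_type == e, ]
  expect_equal(get(ev[1])$peak, 0.5); expect_equal(get(ev[1])$peak_lag, 4.5)
  expect_equal(get(ev[2])$peak, -0.6)
  expect_equal(get(ev[3])$peak_lag, 1.5)
  # the signed-max convention takes the maximum signed value instead
  pk2 <- extract_peak_scores(make_curveset(est), convention = "max")
  expect_equal(pk2[pk2$event_type == ev[4], ]$peak, 0.3)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.0533333333, 0.5), tolerance = 1e-9)
  expect_equal(fdr_adjust(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(42)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- fdr_adjust(p)
    expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH controls the false discovery proportion under the full null", {
  set.seed(7)
  any_disc <- vapply(1:200, function(r) any(fdr_adjust(runif(20)) < 0.05), TRUE)
  expect_lte(mean(any_disc), 0.08)
})

test_that("rank regression rejects degenerate inputs", {
  ev <- event_types(response_only = TRUE)
  set.seed(3)
  n <- 20
  cov <- data.frame(subject_id = sprintf("s%02d", 1:n), group = "case",
                    age = rnorm(n), sex = sample(c("M", "F"), n, TRUE),
                    total_brain_volume = rnorm(n),
                    mean_framewise_displacement = runif(n),
                    handedness = sample(c("right", "left"), n, TRUE),
                    accuracy = 0.5, stringsAsFactors = FALSE)
  peaks <- expand.grid(subject = cov$subject_id, component = "PC1",
                       event_type = ev, stringsAsFactors = FALSE)
  peaks$peak <- rnorm(nrow(peaks)); peaks$peak_lag <- 4.5
  expect_error(rank_accuracy_regression(peaks, cov), "zero variance")
  cov$accuracy <- runif(n)
  expect_error(rank_accuracy_regression(peaks[peaks$subject %in% cov$subject_id[1:5], ],
                                        cov), "fewer than 10")
  res <- rank_accuracy_regression(peaks, cov)
  expect_equal(nrow(res), 4)
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("beta sign is invariant to affine rescaling of accuracy", {
  ev <- event_types(response_only = TRUE)
  set.seed(4)
  n <- 30
  cov <- data.frame(subject_id = sprintf("s%02d", 1:n), group = "case",
                    age = rnorm(n), sex = sample(c("M", "F"), n, TRUE),
                    total_brain_volume = rnorm(n),
                    mean_framewise_displacement = runif(n),
                    handedness = sample(c("right", "left"), n, TRUE),
                    accuracy = runif(n), stringsAsFactors = FALSE)
  peaks <- expand.grid(subject = cov$subject_id, component = "PC1",
                       event_type = ev, stringsAsFactors = FALSE)
  peaks$peak <- cov$accuracy[match(peaks$subject, cov$subject_id)] + rnorm(nrow(peaks), 0, 0.3)
  peaks$peak_lag <- 4.5
  r1 <- rank_accuracy_regression(peaks, cov)
  cov2 <- cov; cov2$accuracy <- 100 * cov$accuracy - 17
  r2 <- rank_accuracy_regression(peaks, cov2)
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_true(all(r1$beta > 0))
})
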