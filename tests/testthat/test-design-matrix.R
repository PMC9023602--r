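events_df <- function(onset, stim, resp)
  data.frame(onset = onset, duration = 5.5, stimulus_class = stim,
             response_class = resp, stringsAsFactors = FALSE)

test_that("events round-trip through BIDS-style TSV", {
  s <- generate_event_schedule(rng_seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(s, path)
  ev <- read_events(path)
  expect_equal(nrow(ev), 60)
  expect_equal(ev$onset, s$onset)
  expect_equal(ev$stimulus_class, s$stimulus_class)
})

test_that("malformed event tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- events_df(c(1, 10), c("threat", "neutral"), c("correct", "correct"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_events(path), "neutral")
  expect_error(as_event_table(df[, -1]), "onset")
  expect_error(as_event_table(df[0, ]), "no trials")
  expect_error(as_event_table(events_df("x", "threat", "correct")), "unparseable")
  expect_error(read_events(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("FIR design has six lags per event type over an 18 s window at TR 3", {
  ev <- as_event_table(events_df(c(0, 30), c("threat", "non-threat"),
                                 c("correct", "incorrect")))
  d <- build_fir_design(ev, n_volumes = 20, repetition_time = 3, window = 18)
  expect_equal(ncol(d$G), 36)
  expect_equal(d$n_lags, 6)
  expect_equal(d$lag_times, c(1.5, 4.5, 7.5, 10.5, 13.5, 16.5))
  expect_true(all(d$G %in% c(0, 1)))
  expect_error(build_fir_design(ev, 20, 3, window = 17), "multiple")
})

test_that("a single trial at onset zero gives an identity block over its lags", {
  ev <- as_event_table(events_df(0, "threat", "correct"))
  d <- build_fir_design(ev, n_volumes = 10, repetition_time = 3, window = 18)
  block <- d$G[1:6, grep("^threat_correct", colnames(d$G))]
  expect_equal(unname(block), diag(6))
  expect_true(all(d$G[, grep("^threat_correct", colnames(d$G), invert = TRUE)] == 0))
})

test_that("overlapping same-type trials superimpose: hand-placed 9 s spacing", {
  ev <- as_event_table(events_df(c(0, 9), c("threat", "threat"),
                                 c("correct", "correct")))
  d <- build_fir_design(ev, n_volumes = 12, repetition_time = 3, window = 18)
  cols <- grep("^threat_correct", colnames(d$G))
  expect_equal(unname(colSums(d$G[, cols])), rep(2, 6))
  # brute-force placement: trial 1 occupies volumes 0..5 (lags 0..5), trial 2
  # occupies volumes 3..8; volumes 3..5 carry two 1s in different lag columns
  for (j in 0:5) expect_equal(which(d$G[, cols[j + 1]] == 1), c(j, j + 3) + 1)
  expect_equal(unname(rowSums(d$G))[4:6], rep(2, 3))
})

test_that("row sums equal the number of trial windows covering each acquisition", {
  s <- generate_event_schedule(n_trials = 20, run_duration = 300, rng_seed = 9)
  d <- build_fir_design(s, 100, 3, 18)
  cover <- sapply(0:99, function(k)
    sum(s$onset <= k * 3 + 1e-9 & k * 3 < s$onset + 18 - 1e-9))
  expect_equal(unname(rowSums(d$G)), cover)
})

test_that("design construction is invariant to trial order", {
  s <- generate_event_schedule(n_trials = 15, run_duration = 250, rng_seed = 10)
  d1 <- build_fir_design(s, 83, 3, 18)
  perm <- as.data.frame(s)[sample(15), ]
  perm <- perm[order(perm$onset), ]  # event_table requires sorted onsets
  d2 <- build_fir_design(as_event_table(perm), 83, 3, 18)
  expect_identical(d1$G, d2$G)
})

test_that("conditioning report flags absent event types and collinear schedules", {
  s <- generate_event_schedule(
    n_trials = 30, run_duration = 630,
    class_probabilities = list(response = c(correct = 1, incorrect = 0,
                                            `non-response` = 0)),
    rng_seed = 11)
  d <- build_fir_design(s, 210, 3, 18)
  rep1 <- check_design_conditioning(d)
  expect_false(rep1$full_rank)
  expect_setequal(rep1$absent_event_types,
                  c("threat_incorrect", "threat_non-response",
                    "non-threat_incorrect", "non-threat_non-response"))
  # trials of one type at exactly TR spacing: every lag column is (almost) the
  # same all-ones indicator, a pathologically collinear design
  ev <- as_event_table(events_df(seq(0, 177, by = 3), "threat", "correct"))
  d2 <- build_fir_design(ev, 65, 3, 18)
  rep2 <- check_design_conditioning(d2)
  expect_true(rep2$collinear)
  # a well-populated generator schedule is full column rank
  s3 <- generate_event_schedule(
    class_probabilities = list(response = c(correct = 0.5, incorrect = 0.3,
                                            `non-response` = 0.2)),
    rng_seed = 12)
  rep3 <- check_design_conditioning(build_fir_design(s3, 210, 3, 18))
  expect_true(rep3$full_rank)
  expect_false(rep3$collinear)
})
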