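# Fixtures are built in code; nothing is read from disk.

# Single-component noiseless model: identical HRF-like bump for every event
# type, unit subject amplitudes. Exact deconvolution testbed.
noiseless_model <- function(n_regions = 30, map_seed = 5) {
  lag <- (1:6 - 0.5) * 3
  V <- orthonormal_maps(1, n_regions, rng_seed = map_seed)
  curves <- array(0, c(1, 6, 6), dimnames = list(NULL, event_types(), NULL))
  for (e in event_types()) curves[1, e, ] <- hrf_bump(lag, 7.5)
  planted_model(V, curves, noise_sd = 0, subject_amplitude_sd = 0,
                region_labels = sprintf("r%03d", seq_len(n_regions)))
}

# Two orthogonal components with orthogonal single-lag curves and a 2:1
# amplitude ratio; with non-overlapping trials the variance split is exactly
# 0.8 / 0.2.
two_component_model <- function(n_regions = 30, map_seed = 6) {
  V <- orthonormal_maps(2, n_regions, rng_seed = map_seed)
  curves <- array(0, c(2, 6, 6), dimnames = list(NULL, event_types(), NULL))
  for (e in event_types()) {
    curves[1, e, ] <- 2 * c(1, 0, 0, 0, 0, 0)
    curves[2, e, ] <- c(0, 1, 0, 0, 0, 0)
  }
  planted_model(V, curves, noise_sd = 0, subject_amplitude_sd = 0)
}

# Schedule config with non-overlapping trials (ISI >= FIR window).
nonoverlap_config <- function(n_trials = 10)
  list(n_trials = n_trials, stimulus_duration = 5.5,
       isi_bounds = c(13, 18.5), run_duration = ceiling(n_trials * 21.5))

# One planted component whose loadings live on a known support (bipolar,
# constant magnitude); everything else is a null region.
support_model <- function(n_regions = 100, support = 1:20, signal_scale = 8) {
  v <- numeric(n_regions)
  v[support] <- rep(c(1, -1), length.out = length(support)) / sqrt(length(support))
  lag <- (1:6 - 0.5) * 3
  curves <- array(0, c(1, 6, 6), dimnames = list(NULL, event_types(), NULL))
  for (e in event_types()) curves[1, e, ] <- hrf_bump(lag, 7.5)
  M <- taskCPCA:::expected_design_gram()
  cv <- as.vector(t(curves[1, , ]))
  cv <- cv / sqrt(sum(cv * (M %*% cv))) * signal_scale
  curves[1, , ] <- matrix(cv, 6, 6, byrow = TRUE)
  planted_model(matrix(v, 1, n_regions), curves,
                noise_sd = 0.6, noise_ar = 0.3, subject_amplitude_sd = 0.3)
}

# Brute-force Benjamini-Hochberg step-up, straight from the definition:
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Average-cohort fixture shared by several files: modest scale, full default
# planted structure.
small_default_cohort <- function(n_per_group = 6, rng_seed = 3) {
  model <- default_planted_model(n_regions = 60, n_cortical = 50, rng_seed = 2)
  suppressWarnings(generate_cohort(n_per_group, n_per_group, model,
                                   rng_seed = rng_seed))
}
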