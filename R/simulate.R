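#' Simulate one subject's parcellated BOLD run
#'
#' The signal is the sum over planted components of (subject amplitude x
#' event-locked response curve placed at every trial of each event type) x
#' spatial map, plus AR(1) noise per region. Curve placement uses exactly the
#' FIR bin rule of [build_fir_design()], so a noiseless run is perfectly
#' deconvolvable.
#'
#' @param schedule a `task_schedule` (or event_table with run metadata).
#' @param model a `planted_model`.
#' @param group "control" or "case"; selects the group-modified curves.
#' @param amplitudes optional per-component subject amplitudes; drawn as
#'   `1 + N(0, subject_amplitude_sd)` when NULL.
#' @param rng_seed integer seed.
#' @return a `parcellated_bold`: list with `data` (volumes x regions),
#'   `repetition_time`, `region_labels`, `cortical`, and attribute
#'   `amplitudes` (the realized per-component amplitudes).
#' @export
generate_subject_bold <- function(schedule, model, group = "control",
                                  amplitudes = NULL, rng_seed = 1L) {
  tr <- model$repetition_time
  if (abs(attr(schedule, "repetition_time") %||% tr - tr) > 1e-9)
    stop_ctx("schedule repetition_time differs from model repetition_time")
  run_duration <- attr(schedule, "run_duration") %||%
    (max(schedule$onset) + model$window + tr)
  n_volumes <- as.integer(round(run_duration / tr))
  K <- nrow(model$spatial_maps); R <- ncol(model$spatial_maps)
  L <- length(model$lag_times)
  design <- build_fir_design(schedule, n_volumes, tr, model$window)
  with_seed(rng_seed, {
    if (is.null(amplitudes))
      amplitudes <- 1 + stats::rnorm(K, 0, model$subject_amplitude_sd)
    S <- matrix(0, n_volumes, K)
    for (k in seq_len(K)) {
      cm <- model_curve(model, k, group)        # event x lag
      beta <- as.vector(t(cm[design$event_types, , drop = FALSE]))
      S[, k] <- design$G %*% (amplitudes[k] * beta)
    }
    gd <- model$global_drift
    if (!is.null(gd) && gd$sd > 0) {
      drift <- as.numeric(stats::filter(stats::rnorm(n_volumes, 0, gd$sd),
                                        gd$ar, method = "recursive"))
      S[, gd$component] <- S[, gd$component] + amplitudes[gd$component] * drift
    }
    X <- S %*% model$spatial_maps
    if (model$noise_sd > 0) {
      innov <- matrix(stats::rnorm(n_volumes * R, 0, model$noise_sd), n_volumes, R)
      noise <- apply(innov, 2, function(e)
        as.numeric(stats::filter(e, model$noise_ar, method = "recursive")))
      X <- X + noise
    }
  })
  if (length(amplitudes) != K) stop_ctx("amplitudes length %d != %d components",
                                        length(amplitudes), K)
  structure(list(data = X, repetition_time = tr,
                 region_labels = model$region_labels,
                 cortical = model$cortical),
            class = "parcellated_bold", amplitudes = amplitudes)
}

#' @export
print.parcellated_bold <- function(x, ...) {
  cat(sprintf("parcellated BOLD: %d volumes x %d regions (TR %.3g s)\n",
              nrow(x$data), ncol(x$data), x$repetition_time))
  invisible(x)
}

#' Simulate a synthetic cohort with known ground truth
#'
#' Generates per-subject task schedules, covariates, accuracy (from the
#' planted behaviour coupling applied to each subject's realized peak
#' amplitudes, plus noise) and parcellated BOLD runs. The returned bundle
#' stores every planted quantity for recovery testing.
#'
#' @param n_cases,n_controls group sizes (study scale: 58 and 58).
#' @param model a `planted_model`.
#' @param config list of schedule options: n_trials (60), stimulus_duration
#'   (5.5), isi_bounds (0.5, 18.5), run_duration (630), start_offset (0),
#'   stimulus_probabilities.
#' @param rng_seed integer master seed; the cohort is a pure function of
#'   (model, config, seed).
#' @return a `cpca_cohort`: list with `subjects` (each: id, group, bold,
#'   events, design), `covariates` data.frame, and `ground_truth`.
#' @export
generate_cohort <- function(n_cases = 58, n_controls = 58, model = default_planted_model(),
                            config = list(), rng_seed = 1L) {
  if (n_cases < 1 || n_controls < 1) stop_ctx("need at least one subject per group")
  cfg <- utils::modifyList(list(n_trials = 60, stimulus_duration = 5.5,
                                isi_bounds = c(0.5, 18.5), run_duration = 630,
                                start_offset = 0,
                                stimulus_probabilities = c(threat = 0.5, `non-threat` = 0.5)),
                           config)
  n <- n_cases + n_controls
  group <- rep(c("case", "control"), c(n_cases, n_controls))
  ids <- sprintf("sub-%03d", seq_len(n))
  K <- nrow(model$spatial_maps); ev <- event_types()
  with_seed(split_seed(rng_seed, "covariates"), {
    age <- ifelse(group == "case", stats::rnorm(n, 20.3, 4.8), stats::rnorm(n, 19.6, 3.9))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    tbv <- ifelse(group == "case", stats::rnorm(n, 1110, 120), stats::rnorm(n, 1220, 120))
    fd <- pmax(0.01, ifelse(group == "case", stats::rnorm(n, 0.119, 0.05),
                            stats::rnorm(n, 0.076, 0.04)))
    hand <- sample(c("right", "left"), n, replace = TRUE, prob = c(0.9, 0.1))
    amplitudes <- matrix(1 + stats::rnorm(n * K, 0, model$subject_amplitude_sd), n, K)
    acc_noise <- stats::rnorm(n)
  })
  # accuracy from planted coupling on realized peak amplitudes; peaks are
  # standardized across the cohort per (component, event type) so the coupling
  # weights are in accuracy units per SD of peak amplitude, independent of the
  # planted signal scale
  peaks <- array(0, dim = c(n, K, length(ev)))
  for (i in seq_len(n)) for (k in seq_len(K)) {
    cm <- model_curve(model, k, group[i])
    peaks[i, k, ] <- amplitudes[i, k] * apply(cm[ev, , drop = FALSE], 1, function(v)
      v[which.max(abs(v))])
  }
  zpeaks <- apply(peaks, c(2, 3), function(v) {
    s <- stats::sd(v)
    if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  })
  accuracy <- numeric(n)
  for (i in seq_len(n)) {
    base <- model$accuracy$base[[if (group[i] == "case") "case" else "control"]]
    sdv <- model$accuracy$sd[[if (group[i] == "case") "case" else "control"]]
    accuracy[i] <- base + sum(model$behavior_coupling * zpeaks[i, , ]) +
      sdv * acc_noise[i]
  }
  accuracy <- pmin(pmax(accuracy, 0.02), 0.995)
  covariates <- data.frame(subject_id = ids, group = group, age = age, sex = sex,
                           total_brain_volume = tbv,
                           mean_framewise_displacement = fd,
                           handedness = hand, accuracy = accuracy,
                           stringsAsFactors = FALSE)
  subjects <- vector("list", n)
  n_volumes <- as.integer(round(cfg$run_duration / model$repetition_time))
  for (i in seq_len(n)) {
    resp_p <- c(correct = accuracy[i],
                incorrect = (1 - accuracy[i]) * 2 / 3,
                `non-response` = (1 - accuracy[i]) / 3)
    sched <- generate_event_schedule(
      n_trials = cfg$n_trials, stimulus_duration = cfg$stimulus_duration,
      isi_bounds = cfg$isi_bounds, run_duration = cfg$run_duration,
      class_probabilities = list(stimulus = cfg$stimulus_probabilities,
                                 response = resp_p),
      repetition_time = model$repetition_time, start_offset = cfg$start_offset,
      rng_seed = split_seed(rng_seed, paste0("schedule", i)))
    bold <- generate_subject_bold(sched, model, group = group[i],
                                  amplitudes = amplitudes[i, ],
                                  rng_seed = split_seed(rng_seed, paste0("bold", i)))
    design <- build_fir_design(sched, n_volumes, model$repetition_time, model$window)
    subjects[[i]] <- list(id = ids[i], group = group[i], bold = bold,
                          events = sched, design = design)
  }
  structure(list(subjects = subjects, covariates = covariates,
                 ground_truth = list(model = model, amplitudes = amplitudes,
                                     accuracy = accuracy, seed = rng_seed,
                                     config = cfg)),
            class = "cpca_cohort")
}

#' @export
print.cpca_cohort <- function(x, ...) {
  tab <- table(x$covariates$group)
  cat(sprintf("synthetic cohort: %d subjects (%s)\n", nrow(x$covariates),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Synthetic parcel centroid coordinates
#'
#' Cortical parcels are placed on a sphere of radius 70 mm, subcortical
#' parcels inside a smaller central shell; purely geometric scaffolding for
#' spatial-autocorrelation modelling of synthetic maps.
#'
#' @param n_regions,n_cortical parcellation size.
#' @param rng_seed integer seed.
#' @return data.frame region, x, y, z, cortical.
#' @export
parcel_centroids <- function(n_regions = 214, n_cortical = 200, rng_seed = 11L) {
  with_seed(rng_seed, {
    p <- matrix(stats::rnorm(3 * n_regions), n_regions, 3)
    p <- p / sqrt(rowSums(p^2))
    r <- c(rep(70, n_cortical), rep(25, n_regions - n_cortical))
    p <- p * r
  })
  data.frame(region = sprintf("region_%03d", seq_len(n_regions)),
             x = p[, 1], y = p[, 2], z = p[, 3],
             cortical = seq_len(n_regions) <= n_cortical)
}

#' Simulate regional structural difference maps
#'
#' Two cortical difference maps (cortical thickness and cortical surface
#' area analogues). Both start as spatially smooth noise (kernel-smoothed over
#' inter-centroid distances); the surface-area map additionally carries
#' `effect_size` times the absolute loadings of the designated truth
#' component, so that map-alignment tests have a known positive and a known
#' null condition.
#'
#' @param model a `planted_model` (supplies loadings and the cortical flags).
#' @param truth_component component index whose |loadings| are planted into
#'   the surface-area map, or NA for a fully null pair.
#' @param effect_size planted effect magnitude in SD units of the smooth noise.
#' @param spatial_autocorr_length kernel length scale in mm.
#' @param centroids optional centroid table from [parcel_centroids()].
#' @param rng_seed integer seed.
#' @return list with `thickness` and `surface_area`, each a `structural_map`
#'   data.frame (region, value, x, y, z) over cortical regions only.
#' @export
generate_structural_maps <- function(model, truth_component = NA,
                                     effect_size = 0,
                                     spatial_autocorr_length = 30,
                                     centroids = NULL, rng_seed = 1L) {
  R <- ncol(model$spatial_maps)
  cortical <- model$cortical
  cen <- centroids %||% parcel_centroids(R, sum(cortical))
  cen <- cen[cortical, , drop = FALSE]
  D <- as.matrix(stats::dist(cen[, c("x", "y", "z")]))
  Kmat <- exp(-D / spatial_autocorr_length)
  smooth_field <- function() {
    v <- as.numeric(Kmat %*% stats::rnorm(nrow(Kmat)))
    as.numeric(scale(v))
  }
  with_seed(rng_seed, {
    thickness <- smooth_field()
    sa <- smooth_field()
  })
  if (!is.na(truth_component) && effect_size != 0) {
    ld <- abs(model$spatial_maps[truth_component, cortical])
    sa <- sa + effect_size * as.numeric(scale(ld))
  }
  mk <- function(v, metric) {
    structure(data.frame(region = cen$region, value = v,
                         x = cen$x, y = cen$y, z = cen$z,
                         stringsAsFactors = FALSE),
              metric = metric, class = c("structural_map", "data.frame"))
  }
  list(thickness = mk(thickness, "cortical_thickness"),
       surface_area = mk(sa, "cortical_surface_area"))
}
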