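#' Construct a planted ground-truth model for synthetic cohorts
#'
#' A planted model fixes everything the synthetic-data generator needs:
#' orthonormal spatial maps (components x regions), event-locked response
#' curves (component x event type x lag, evaluated at acquisition-bin
#' midpoints), multiplicative case-group curve modifications, AR(1) noise,
#' between-subject amplitude spread, and a coupling matrix that links each
#' subject's realized peak amplitudes to task accuracy.
#'
#' @param spatial_maps components x regions matrix; rows must be mutually
#'   orthogonal and unit norm.
#' @param response_curves components x event types x lags array; dimnames on
#'   the second margin must be the six event types.
#' @param group_effects list with `scale` (per-component multiplier applied to
#'   case-group curves, default 1) and `lag_mask` (components x lags
#'   multiplicative mask for case-group curves, default all 1).
#' @param noise_ar lag-1 autoregressive coefficient of the regional noise,
#'   in (-1, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise.
#' @param subject_amplitude_sd SD of the per-subject, per-component
#'   multiplicative amplitude (mean 1).
#' @param behavior_coupling components x event types matrix of weights linking
#'   a subject's realized peak amplitude on (component, event type) to their
#'   task accuracy; default all zero.
#' @param accuracy list with `base` (named: case, control), `sd` (named), the
#'   intercept and noise of the accuracy model.
#' @param repetition_time,window seconds; define the lag grid
#'   (lags at midpoints TR/2, 3TR/2, ...).
#' @param region_labels,cortical region names and a logical flag marking
#'   cortical regions (structural metrics exist only there).
#' @param global_drift optional list(component, ar, sd): the designated
#'   component carries a slow AR(ar) global fluctuation of innovation SD `sd`
#'   instead of (or on top of) an event-locked response, emulating the global
#'   signal component that task-variance extraction partially captures.
#' @return object of class `planted_model`.
#' @export
planted_model <- function(spatial_maps, response_curves,
                          group_effects = list(),
                          noise_ar = 0.3, noise_sd = 1,
                          subject_amplitude_sd = 0.3,
                          behavior_coupling = NULL,
                          accuracy = list(base = c(case = 0.729, control = 0.909),
                                          sd = c(case = 0.10, control = 0.05)),
                          repetition_time = 3, window = 18,
                          region_labels = NULL, cortical = NULL,
                          global_drift = NULL) {
  K <- nrow(spatial_maps); R <- ncol(spatial_maps)
  L <- dim(response_curves)[3]
  stopifnot(dim(response_curves)[1] == K,
            dim(response_curves)[2] == length(event_types()))
  G <- spatial_maps %*% t(spatial_maps)
  if (max(abs(G - diag(K))) > 1e-8)
    stop_ctx("spatial_maps rows must be orthonormal (max deviation %.2g)",
             max(abs(G - diag(K))))
  if (abs(noise_ar) >= 1) stop_ctx("noise AR coefficient must lie in (-1, 1)")
  n_lags_expected <- window / repetition_time
  if (abs(n_lags_expected - round(n_lags_expected)) > 1e-9 || L != round(n_lags_expected))
    stop_ctx("lag grid inconsistent: window %.3g / TR %.3g != %d curve lags",
             window, repetition_time, L)
  ge <- list(scale = group_effects$scale %||% rep(1, K),
             lag_mask = group_effects$lag_mask %||% matrix(1, K, L))
  stopifnot(length(ge$scale) == K, all(dim(ge$lag_mask) == c(K, L)))
  bc <- behavior_coupling %||% matrix(0, K, length(event_types()))
  if (!is.null(global_drift)) {
    stopifnot(global_drift$component %in% seq_len(K),
              abs(global_drift$ar) < 1, global_drift$sd >= 0)
  }
  structure(list(
    global_drift = global_drift,
    spatial_maps = spatial_maps,
    response_curves = response_curves,
    group_effects = ge,
    noise_ar = noise_ar, noise_sd = noise_sd,
    subject_amplitude_sd = subject_amplitude_sd,
    behavior_coupling = bc,
    accuracy = accuracy,
    repetition_time = repetition_time, window = window,
    lag_times = (seq_len(L) - 0.5) * repetition_time,
    region_labels = region_labels %||% sprintf("region_%03d", seq_len(R)),
    cortical = cortical %||% rep(TRUE, R)
  ), class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat(sprintf("planted model: %d components x %d regions, %d lags (TR %.3g s)\n",
              nrow(x$spatial_maps), ncol(x$spatial_maps),
              length(x$lag_times), x$repetition_time))
  cat(sprintf("noise: AR(1) phi = %.3g, innovation sd = %.3g; subject amplitude sd = %.3g\n",
              x$noise_ar, x$noise_sd, x$subject_amplitude_sd))
  invisible(x)
}

#' Gaussian bump on the continuous post-event time axis
#'
#' Evaluated at the acquisition-bin midpoints; a simple HRF-like shape for
#' constructing planted response curves.
#'
#' @param lag_times bin midpoints in seconds.
#' @param peak peak time in seconds.
#' @param width Gaussian width in seconds.
#' @param amplitude peak amplitude.
#' @return numeric vector over `lag_times`.
#' @export
hrf_bump <- function(lag_times, peak, width = 2.5, amplitude = 1) {
  amplitude * exp(-0.5 * ((lag_times - peak) / width)^2)
}

#' Build mutually orthonormal spatial maps
#'
#' Random orthonormal rows via QR of a Gaussian matrix; optionally the first
#' row is a near-uniform all-positive map emulating a global signal component
#' (the remaining rows are orthogonalized against it).
#'
#' @param n_components,n_regions dimensions.
#' @param include_global logical; make component 1 a same-sign global map.
#' @param rng_seed integer seed.
#' @return n_components x n_regions matrix with orthonormal rows.
#' @export
orthonormal_maps <- function(n_components, n_regions, include_global = FALSE,
                             rng_seed = 1L) {
  with_seed(rng_seed, {
    M <- matrix(stats::rnorm(n_regions * n_components), n_regions, n_components)
    if (include_global) M[, 1] <- 1 + 0.15 * stats::runif(n_regions)
  })
  Q <- qr.Q(qr(M))
  # QR can flip signs; make the global column all-positive again and give each
  # map a positive largest-|loading| entry for reproducibility
  V <- t(Q)
  for (k in seq_len(n_components)) {
    j <- which.max(abs(V[k, ]))
    if (V[k, j] < 0) V[k, ] <- -V[k, ]
  }
  if (include_global && any(V[1, ] < 0) && mean(V[1, ] > 0) < 0.5) V[1, ] <- -V[1, ]
  V
}

#' Default planted model emulating the emotion-identification study conditions
#'
#' Five task components plus an optional global component over 214 regions
#' (200 cortical + 14 subcortical). The planted response curves reproduce the
#' qualitative component phenomenology: an early-peaking sensorimotor-like
#' component (peak ~7.5 s), a delayed error-sensitive component (~10.5 s,
#' largest on incorrect trials), a valence component with a positive correct
#' peak and negative incorrect dip, an early salience-like component largest
#' on incorrect trials, and a biphasic component (negative ~4.5 s, positive
#' ~13.5 s) whose late peak is removed in the case group. Behaviour coupling
#' links the delayed error-sensitive component's incorrect-trial peaks to
#' accuracy.
#'
#' Because principal components are orthogonal by construction, a planted
#' decomposition is identifiable only when the planted temporal profiles are
#' themselves (near-)orthogonal; the qualitative curve shapes are therefore
#' orthogonalized across components (Gram-Schmidt, weighted by the expected
#' event-type frequencies) and given strictly decreasing amplitudes so the
#' planted variance order is well defined.
#'
#' @param n_regions,n_cortical parcellation size (default 214 = 200 + 14).
#' @param n_components number of task components (default 5).
#' @param include_global add a same-sign global component (default TRUE).
#' @param signal_scale common multiplier on all planted curves; the default
#'   gives a task-related variance fraction near 0.2 under the default noise.
#' @param noise_sd,noise_ar,subject_amplitude_sd noise configuration.
#' @param behavior_coupling optional override of the coupling matrix.
#' @param rng_seed integer seed for the random orthonormal maps.
#' @return a `planted_model`.
#' @export
default_planted_model <- function(n_regions = 214, n_cortical = 200,
                                  n_components = 5, include_global = TRUE,
                                  signal_scale = 8,
                                  noise_sd = 0.6, noise_ar = 0.3,
                                  subject_amplitude_sd = 0.3,
                                  behavior_coupling = NULL,
                                  rng_seed = 1L) {
  K <- n_components + include_global
  V <- orthonormal_maps(K, n_regions, include_global = include_global,
                        rng_seed = rng_seed)
  tr <- 3; lag_times <- (1:6 - 0.5) * tr
  ev <- event_types()
  curves <- array(0, dim = c(K, length(ev), 6),
                  dimnames = list(NULL, ev, NULL))
  shapes <- list(
    pc1 = function(e) hrf_bump(lag_times, 7.5,
                               amplitude = if (e == "threat_correct") 1.2 else 1),
    pc2 = function(e) hrf_bump(lag_times, 10.5,
                               amplitude = if (grepl("incorrect", e)) 1.2 else 0.5),
    pc3 = function(e) {
      a <- if (grepl("^threat", e)) 1.2 else 0.8
      if (grepl("_correct", e)) hrf_bump(lag_times, 10.5, amplitude = a)
      else -hrf_bump(lag_times, 7.5, amplitude = 0.8 * a)
    },
    pc4 = function(e) hrf_bump(lag_times, 7.5,
                               amplitude = if (grepl("incorrect", e)) 1.1 else 0.7),
    pc5 = function(e) hrf_bump(lag_times, 13.5, width = 2, amplitude = 0.9) -
                      hrf_bump(lag_times, 4.5, width = 2, amplitude = 0.6)
  )
  offset <- as.integer(include_global)
  for (k in seq_len(n_components)) {
    f <- shapes[[((k - 1) %% length(shapes)) + 1]]
    for (e in ev) curves[k + offset, e, ] <- f(e)
  }
  # Orthogonalize the concatenated event x lag profiles across task components
  # in the metric of the expected centered design Gram E[G'HG] (trial overlap
  # makes placed time courses correlated even for orthogonal curve vectors,
  # and per-region centering in the analysis removes each course's DC part),
  # so the planted decomposition is identifiable; then impose strictly
  # decreasing amplitudes so the planted variance order is well defined.
  M <- expected_design_gram(repetition_time = tr, window = 18)
  task <- offset + seq_len(n_components)
  Cmat <- t(apply(curves, 1, function(m) as.vector(t(m))))  # K x (event*lag)
  amp <- 1.4^(n_components - seq_len(n_components))
  for (i in seq_along(task)) {
    k <- task[i]
    v <- Cmat[k, ]
    if (i > 1) for (j in task[seq_len(i - 1)])
      v <- v - sum(v * (M %*% Cmat[j, ])) / sum(Cmat[j, ] * (M %*% Cmat[j, ])) * Cmat[j, ]
    Cmat[k, ] <- v / sqrt(sum(v * (M %*% v))) * amp[i]
    curves[k, , ] <- matrix(Cmat[k, ], length(ev), 6, byrow = TRUE)
  }
  curves <- curves * signal_scale
  # the global component is a slow shared fluctuation, not an evoked response;
  # its drift scale tracks signal_scale so one knob moves the whole SNR
  drift <- if (include_global)
    list(component = 1L, ar = 0.95, sd = 0.45 * signal_scale) else NULL
  # case-group modifications: attenuated error component, late peak removed
  # from the biphasic component
  scale <- rep(1, K); lag_mask <- matrix(1, K, 6)
  if (n_components >= 2) scale[2 + offset] <- 0.7
  if (n_components >= 5) lag_mask[5 + offset, 5:6] <- 0
  bc <- behavior_coupling
  if (is.null(bc)) {
    bc <- matrix(0, K, length(ev), dimnames = list(NULL, ev))
    if (n_components >= 2)
      bc[2 + offset, c("threat_incorrect", "non-threat_incorrect")] <- 0.15
  }
  planted_model(
    spatial_maps = V,
    response_curves = curves,
    group_effects = list(scale = scale, lag_mask = lag_mask),
    noise_ar = noise_ar, noise_sd = noise_sd,
    subject_amplitude_sd = subject_amplitude_sd,
    behavior_coupling = bc,
    repetition_time = tr, window = 18,
    region_labels = sprintf("region_%03d", seq_len(n_regions)),
    cortical = seq_len(n_regions) <= n_cortical,
    global_drift = drift
  )
}

# Expected FIR design Gram matrix E[G'G] under the default task geometry,
# averaged over seeded schedule draws; used as the inner product in which
# planted curves are orthogonalized. Memoised per (TR, window).
expected_design_gram <- local({
  cache <- list()
  function(repetition_time = 3, window = 18, n_draws = 40) {
    key <- paste(repetition_time, window, n_draws)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_vol <- as.integer(round(630 / repetition_time))
    M <- 0
    # average over schedules with accuracies drawn from both cohort regimes
    # (Gram entries are nonlinear in the event-type proportions, so the
    # accuracy spread matters, not just its mean)
    accs <- with_seed(77003L, pmin(pmax(
      ifelse(seq_len(n_draws) %% 2 == 0,
             stats::rnorm(n_draws, 0.729, 0.10),
             stats::rnorm(n_draws, 0.909, 0.05)), 0.02), 0.995))
    for (s in seq_len(n_draws)) {
      acc <- accs[s]
      sched <- generate_event_schedule(
        repetition_time = repetition_time,
        class_probabilities = list(response = c(correct = acc,
                                                incorrect = (1 - acc) * 2 / 3,
                                                `non-response` = (1 - acc) / 3)),
        rng_seed = 90000L + s)
      G <- build_fir_design(sched, n_vol, repetition_time, window)$G
      # centered Gram: per-region centering in the analysis removes the DC
      # part of every placed course, so orthogonality/energy must be measured
      # on centered courses
      M <- M + crossprod(scale(G, center = TRUE, scale = FALSE))
    }
    M <- M / n_draws
    cache[[key]] <<- M
    M
  }
})

# Case/control response curve for one component: event x lag matrix.
model_curve <- function(model, component, group) {
  cm <- model$response_curves[component, , , drop = TRUE]
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = length(event_types()),
                                     dimnames = list(event_types(), NULL))
  if (group == "case")
    cm <- model$group_effects$scale[component] *
      sweep(cm, 2, model$group_effects$lag_mask[component, ], `*`)
  cm
}
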