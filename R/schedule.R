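#' Event-type vocabulary
#'
#' The six task events are the cross of stimulus class (threat / non-threat)
#' and response class (correct / incorrect / non-response). The first four
#' (the response events) are the ones modelled in growth models and
#' brain-behaviour analyses.
#'
#' @param response_only logical; return only the four response events.
#' @return character vector of event-type labels.
#' @export
event_types <- function(response_only = FALSE) {
  resp <- if (response_only) c("correct", "incorrect")
          else c("correct", "incorrect", "non-response")
  as.vector(outer(stimulus_classes(), resp, paste, sep = "_"))
}

#' @rdname event_types
#' @export
stimulus_classes <- function() c("threat", "non-threat")

#' @rdname event_types
#' @export
response_classes <- function() c("correct", "incorrect", "non-response")

#' Generate a jittered fast event-related task schedule
#'
#' Emulates a fast event-related emotion-identification run: `n_trials`
#' stimuli of fixed duration separated by jittered inter-stimulus intervals
#' (ISIs). ISIs are drawn uniformly within `isi_bounds` and then affinely
#' rescaled (preserving their ordering and spread as far as the bounds allow)
#' so that the run fills `run_duration` exactly. Each trial carries a
#' stimulus class and a response class sampled from `class_probabilities`.
#'
#' @param n_trials number of trials (default 60).
#' @param stimulus_duration stimulus presentation time in seconds (default 5.5).
#' @param isi_bounds length-2 numeric, ISI bounds in seconds (default 0.5-18.5).
#' @param run_duration total run length in seconds (default 630, i.e. 10.5 min).
#' @param class_probabilities list with elements `stimulus` (named
#'   probabilities over threat/non-threat) and `response` (named probabilities
#'   over correct/incorrect/non-response).
#' @param repetition_time TR in seconds, carried as metadata (default 3).
#' @param start_offset seconds before the first trial onset (default 0).
#' @param rng_seed integer seed; the schedule is a pure function of the
#'   arguments and this seed.
#' @return a `task_schedule`: data.frame with columns onset, duration,
#'   stimulus_class, response_class and attributes run_duration,
#'   repetition_time.
#' @export
generate_event_schedule <- function(n_trials = 60,
                                    stimulus_duration = 5.5,
                                    isi_bounds = c(0.5, 18.5),
                                    run_duration = 630,
                                    class_probabilities = NULL,
                                    repetition_time = 3,
                                    start_offset = 0,
                                    rng_seed = 1L) {
  if (length(isi_bounds) != 2 || isi_bounds[1] > isi_bounds[2])
    stop_ctx("isi_bounds must be an ordered pair, got (%s)", paste(isi_bounds, collapse = ", "))
  if (n_trials < 1) stop_ctx("n_trials must be >= 1")
  occupied <- n_trials * stimulus_duration + start_offset
  if (occupied >= run_duration)
    stop_ctx("infeasible schedule: %d trials of %.3g s (+%.3g s offset) need %.4g s but run_duration is %.4g s",
             n_trials, stimulus_duration, start_offset, occupied, run_duration)
  target_mean <- (run_duration - occupied) / n_trials
  if (target_mean < isi_bounds[1] || target_mean > isi_bounds[2])
    stop_ctx("infeasible schedule: required mean ISI %.4g s lies outside isi_bounds (%.3g, %.3g)",
             target_mean, isi_bounds[1], isi_bounds[2])
  probs <- class_probabilities %||% list()
  p_stim <- probs$stimulus %||% c(threat = 0.5, `non-threat` = 0.5)
  p_resp <- probs$response %||% c(correct = 0.8, incorrect = 0.13, `non-response` = 0.07)
  with_seed(rng_seed, {
    u <- stats::runif(n_trials, isi_bounds[1], isi_bounds[2])
    if (n_trials == 1) {
      isi <- target_mean
    } else {
      # shrink spread just enough that the affinely shifted ISIs stay in bounds
      dev <- u - mean(u)
      beta <- min(1,
                  if (min(dev) < 0) (target_mean - isi_bounds[1]) / (-min(dev)) else 1,
                  if (max(dev) > 0) (isi_bounds[2] - target_mean) / max(dev) else 1)
      isi <- target_mean + beta * dev
    }
    onsets <- start_offset + cumsum(c(0, (stimulus_duration + isi)[-n_trials]))
    stim <- sample(stimulus_classes(), n_trials, replace = TRUE,
                   prob = p_stim[stimulus_classes()])
    resp <- sample(response_classes(), n_trials, replace = TRUE,
                   prob = p_resp[response_classes()])
  })
  out <- data.frame(onset = onsets,
                    duration = stimulus_duration,
                    stimulus_class = stim,
                    response_class = resp,
                    stringsAsFactors = FALSE)
  attr(out, "run_duration") <- run_duration
  attr(out, "repetition_time") <- repetition_time
  class(out) <- c("task_schedule", "data.frame")
  validate_task_schedule(out, isi_bounds)
  out
}

validate_task_schedule <- function(schedule, isi_bounds = NULL) {
  on <- schedule$onset
  if (any(diff(on) <= 0)) stop_ctx("schedule onsets must be strictly increasing")
  rd <- attr(schedule, "run_duration")
  if (utils::tail(on, 1) + utils::tail(schedule$duration, 1) > rd + 1e-9)
    stop_ctx("last trial window does not fit inside run_duration")
  if (!is.null(isi_bounds) && nrow(schedule) > 1) {
    isi <- diff(on) - schedule$duration[-nrow(schedule)]
    if (any(isi < isi_bounds[1] - 1e-9 | isi > isi_bounds[2] + 1e-9))
      stop_ctx("ISIs fall outside the configured bounds")
  }
  invisible(schedule)
}
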