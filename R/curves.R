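#' Estimate event-locked response curves for one subject
#'
#' Back-regression: the subject's component score time series are regressed
#' on the same FIR basis used for extraction, giving the mean component score
#' at each post-event acquisition for each event type. Event types absent for
#' the subject (all-zero design columns) are returned as NA (absent), not
#' zero.
#'
#' @param scores volumes x components score matrix for one subject.
#' @param design the subject's `fir_design`.
#' @return array event_type x lag x component with NA entries for absent
#'   event types; attributes `lag_times` and `event_types`.
#' @export
estimate_response_curves <- function(scores, design) {
  scores <- as.matrix(scores)
  G <- design$G
  if (nrow(scores) != nrow(G))
    stop_ctx("score rows (%d) must equal design rows (%d)", nrow(scores), nrow(G))
  zero <- colSums(abs(G)) == 0
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  B <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% scores) / sv$d[pos])
  B[zero, ] <- NA_real_
  L <- design$n_lags
  ev <- design$event_types
  out <- array(NA_real_, dim = c(length(ev), L, ncol(scores)),
               dimnames = list(ev, paste0("lag", seq_len(L) - 1),
                               colnames(scores)))
  for (k in seq_len(ncol(scores)))
    out[, , k] <- matrix(B[, k], length(ev), L, byrow = TRUE)
  attr(out, "lag_times") <- design$lag_times
  attr(out, "event_types") <- ev
  out
}

#' Estimate response curves for every subject of a CPCA fit
#'
#' @param fit a `cpca` fit (its stored per-subject designs are reused,
#'   honouring the "same FIR basis set" convention).
#' @return a `response_curve_set`: list with `estimates` (subject x component
#'   x event type x lag array, NA marking absent event types), `lag_times`,
#'   `event_types`, `subject_ids`, `component_labels`.
#' @export
response_curves <- function(fit) {
  stopifnot(inherits(fit, "cpca"))
  n <- length(fit$scores)
  L <- fit$designs[[1]]$n_lags
  ev <- fit$designs[[1]]$event_types
  K <- fit$n_components
  est <- array(NA_real_, dim = c(n, K, length(ev), L),
               dimnames = list(fit$subject_ids, fit$component_labels, ev,
                               paste0("lag", seq_len(L) - 1)))
  for (i in seq_len(n)) {
    a <- estimate_response_curves(fit$scores[[i]], fit$designs[[i]])
    est[i, , , ] <- aperm(a, c(3, 1, 2))
  }
  structure(list(estimates = est,
                 lag_times = fit$designs[[1]]$lag_times,
                 event_types = ev,
                 subject_ids = fit$subject_ids,
                 component_labels = fit$component_labels),
            class = "response_curve_set")
}

#' @export
print.response_curve_set <- function(x, ...) {
  d <- dim(x$estimates)
  cat(sprintf("response curves: %d subjects x %d components x %d event types x %d lags\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Long-format view of a response curve set
#' @param x a `response_curve_set`.
#' @param ... unused.
#' @return data.frame: subject, component, event_type, stimulus_class,
#'   response_class, lag_time_s, estimate (absent entries dropped).
#' @export
as.data.frame.response_curve_set <- function(x, ...) {
  d <- dim(x$estimates)
  df <- expand.grid(subject = x$subject_ids,
                    component = x$component_labels,
                    event_type = x$event_types,
                    lag = seq_len(d[4]),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$lag_time_s <- x$lag_times[df$lag]
  df$estimate <- as.vector(x$estimates)  # array order matches expand.grid order
  parts <- strsplit(df$event_type, "_")
  df$stimulus_class <- vapply(parts, `[[`, "", 1)
  df$response_class <- vapply(parts, `[[`, "", 2)
  df$lag <- NULL
  df[!is.na(df$estimate), , drop = FALSE]
}

#' Group mean and SE response curves
#'
#' @param curves a `response_curve_set`.
#' @param groups named character vector (or factor) of group labels indexed by
#'   subject id, or a covariates data.frame with subject_id and group columns.
#' @return data.frame: group, component, event_type, lag_time_s, mean, se, n;
#'   subjects with an absent event type are excluded from that cell's
#'   denominator.
#' @export
aggregate_curves <- function(curves, groups) {
  if (is.data.frame(groups))
    groups <- stats::setNames(groups$group, groups$subject_id)
  df <- as.data.frame(curves)
  df$group <- unname(groups[df$subject])
  if (anyNA(df$group)) stop_ctx("group labels missing for some subjects")
  agg <- stats::aggregate(estimate ~ group + component + event_type + lag_time_s,
                          data = df, FUN = function(v)
                            c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)),
                              n = length(v)))
  small <- tapply(df$subject, df$group, function(s) length(unique(s)))
  if (any(small < 2)) stop_ctx("aggregate_curves needs >= 2 subjects per group")
  out <- agg[, 1:4]
  out$mean <- agg$estimate[, "mean"]
  out$se <- agg$estimate[, "se"]
  out$n <- agg$estimate[, "n"]
  out
}
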