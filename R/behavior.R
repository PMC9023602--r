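#' Extract per-subject peak component scores per event type
#'
#' For each (subject, component, response event type), the peak is the signed
#' curve value at the lag with maximal |estimate| (default convention), or the
#' signed maximum with `convention = "max"`. Ties are broken toward the
#' earliest lag. Absent event types stay absent; subjects with no available
#' event type at all are excluded with a message.
#'
#' @param curves a `response_curve_set`.
#' @param convention "absmax" (signed value at the |.|-maximizing lag) or
#'   "max" (signed maximum).
#' @return a `peak_score_table` data.frame: subject, component, event_type,
#'   peak, peak_lag (seconds).
#' @export
extract_peak_scores <- function(curves, convention = c("absmax", "max")) {
  convention <- match.arg(convention)
  ev <- event_types(response_only = TRUE)
  df <- as.data.frame(curves)
  df <- df[df$event_type %in% ev, , drop = FALSE]
  if (!nrow(df)) stop_ctx("no response-event curves available")
  key <- interaction(df$subject, df$component, df$event_type, drop = TRUE)
  rows <- lapply(split(df, key), function(d) {
    crit <- if (convention == "absmax") abs(d$estimate) else d$estimate
    i <- which(crit == max(crit))[1]             # earliest lag wins ties
    data.frame(subject = d$subject[1], component = d$component[1],
               event_type = d$event_type[1], peak = d$estimate[i],
               peak_lag = d$lag_time_s[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  dropped <- setdiff(curves$subject_ids, unique(out$subject))
  if (length(dropped))
    message(sprintf("extract_peak_scores: %d subject(s) excluded (no available curves)",
                    length(dropped)))
  class(out) <- c("peak_score_table", "data.frame")
  out
}

#' Associate peak component scores with ranked task accuracy
#'
#' For each (component, event type) cell, an ordinary least squares model of
#' rank-transformed accuracy (average ranks for ties, then z-scored) on the
#' z-scored peak score plus the mandatory covariates (age, sex, total brain
#' volume, mean framewise displacement, handedness), fit within `group`. The
#' coefficient on the peak is the standardized beta. Benjamini-Hochberg FDR is
#' applied over exactly the tested family (5 components x 4 response events =
#' 20 cells at study scale). Missing peaks are dropped per model.
#'
#' @param peaks a `peak_score_table`.
#' @param covariates data.frame with subject_id, group, accuracy and the
#'   mandatory covariates.
#' @param group group to analyse ("case" by default, per the primary family),
#'   or NULL for all subjects.
#' @param interaction_model also fit, per cell, a both-group model with a
#'   group x peak interaction; its interaction p-value is reported separately
#'   (no joint correction).
#' @return an `association_result` data.frame: component, event_type, beta,
#'   se, p, q, df, n (and interaction_p when requested).
#' @export
rank_accuracy_regression <- function(peaks, covariates, group = "case",
                                     interaction_model = FALSE) {
  cov <- covariates
  if (!is.null(group)) cov <- cov[cov$group %in% group, , drop = FALSE]
  if (stats::var(cov$accuracy) == 0) stop_ctx("outcome has zero variance")
  cov$rank_acc <- as.numeric(scale(rank(cov$accuracy, ties.method = "average")))
  covariate_terms <- c("age", "sex", "total_brain_volume",
                       "mean_framewise_displacement", "handedness")
  constant <- vapply(covariate_terms, function(cc)
    length(unique(cov[[cc]])) < 2, TRUE)
  if (any(constant)) {
    message(sprintf("covariate(s) constant in this sample, dropped: %s",
                    paste(covariate_terms[constant], collapse = ", ")))
    covariate_terms <- covariate_terms[!constant]
  }
  cells <- unique(peaks[, c("component", "event_type")])
  cells <- cells[order(cells$component, cells$event_type), , drop = FALSE]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    d <- peaks[peaks$component == cells$component[i] &
                 peaks$event_type == cells$event_type[i], , drop = FALSE]
    d <- merge(d, cov, by.x = "subject", by.y = "subject_id")
    d <- d[stats::complete.cases(d[, c("peak", "rank_acc", covariate_terms)]), ,
           drop = FALSE]
    if (nrow(d) < 10)
      stop_ctx("fewer than 10 subjects for %s / %s after filtering",
               cells$component[i], cells$event_type[i])
    d$peak_z <- as.numeric(scale(d$peak))
    f <- stats::as.formula(paste("rank_acc ~ peak_z +",
                                 paste(covariate_terms, collapse = " + ")))
    X <- stats::model.matrix(stats::update(f, NULL ~ .), d)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop_ctx("rank-deficient covariates: %s",
               paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
    m <- stats::lm(f, data = d)
    sm <- summary(m)$coefficients["peak_z", ]
    out <- data.frame(component = cells$component[i],
                      event_type = cells$event_type[i],
                      beta = sm[1], se = sm[2], p = sm[4],
                      df = m$df.residual, n = nrow(d), stringsAsFactors = FALSE)
    if (interaction_model) {
      di <- merge(peaks[peaks$component == cells$component[i] &
                          peaks$event_type == cells$event_type[i], ],
                  covariates, by.x = "subject", by.y = "subject_id")
      di$rank_acc <- as.numeric(scale(rank(di$accuracy, ties.method = "average")))
      di$peak_z <- as.numeric(scale(di$peak))
      mi <- stats::lm(rank_acc ~ peak_z * group + age + sex + total_brain_volume +
                        mean_framewise_displacement + handedness, data = di)
      smi <- summary(mi)$coefficients
      ix <- grep("^peak_z:group", rownames(smi))
      out$interaction_p <- if (length(ix)) smi[ix[1], 4] else NA_real_
    }
    out
  })
  out <- do.call(rbind, c(res, make.row.names = FALSE))
  out$q <- fdr_adjust(out$p)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values over the supplied family.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop_ctx("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
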