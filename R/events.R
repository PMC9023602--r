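#' Read a BIDS-style events table
#'
#' Reads a tab-separated events file with columns `onset`, `duration`,
#' `stimulus_class` and `response_class`, validating onsets and the class
#' vocabularies (threat / non-threat; correct / incorrect / non-response).
#'
#' @param path path to an events.tsv file.
#' @return an `event_table` data.frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_ctx("events file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  as_event_table(df, source = path)
}

#' Validate a data.frame as an event table
#'
#' @param df data.frame with onset, stimulus_class, response_class (duration
#'   optional).
#' @param source label used in error messages.
#' @return an `event_table` data.frame.
#' @export
as_event_table <- function(df, source = "events") {
  required <- c("onset", "stimulus_class", "response_class")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_ctx("%s: missing required column(s): %s", source, paste(missing, collapse = ", "))
  if (nrow(df) == 0) stop_ctx("%s: no trials", source)
  onset <- suppressWarnings(as.numeric(df$onset))
  if (anyNA(onset)) {
    bad <- which(is.na(onset))[1]
    stop_ctx("%s: unparseable onset '%s' at row %d", source, df$onset[bad], bad)
  }
  if (any(onset < 0)) stop_ctx("%s: negative onset at row %d", source, which(onset < 0)[1])
  if (is.unsorted(onset, strictly = FALSE))
    stop_ctx("%s: onsets must be non-decreasing", source)
  for (col in c("stimulus_class", "response_class")) {
    vocab <- if (col == "stimulus_class") stimulus_classes() else response_classes()
    bad <- which(!df[[col]] %in% vocab)
    if (length(bad))
      stop_ctx("%s: unknown %s '%s' at row %d (allowed: %s)",
               source, col, df[[col]][bad[1]], bad[1], paste(vocab, collapse = ", "))
  }
  df$onset <- onset
  class(df) <- unique(c("event_table", class(df)))
  df
}

#' Write an events table as BIDS-style TSV
#' @param events an event_table or task_schedule.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  cols <- intersect(c("onset", "duration", "stimulus_class", "response_class"),
                    names(events))
  utils::write.table(as.data.frame(events)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# event label for each trial
trial_event_type <- function(events) {
  paste(events$stimulus_class, events$response_class, sep = "_")
}

#' Build a finite impulse response (FIR) design matrix
#'
#' One indicator column per (event type, post-event acquisition bin):
#' acquisition `k` (covering `[k*TR, (k+1)*TR)`) receives a 1 in the lag-`j`
#' column of event type `e` for every trial of type `e` at onset `t0` with
#' `k*TR - t0` in `[j*TR, (j+1)*TR)`. With a window of 18 s at TR 3 s this
#' yields 6 lags per event type and 36 columns for the six event types.
#' Event types absent from the events table keep their (all-zero) columns so
#' that column blocks align across subjects.
#'
#' @param events an `event_table` (or task_schedule).
#' @param n_volumes number of acquisitions in the run.
#' @param repetition_time TR in seconds.
#' @param window FIR window in seconds; must be a positive multiple of the TR.
#' @return a `fir_design`: list with `G` (volumes x columns 0/1 matrix),
#'   `lag_times` (bin midpoints, seconds), `event_types`, `n_lags`,
#'   `repetition_time`.
#' @export
build_fir_design <- function(events, n_volumes, repetition_time = 3, window = 18) {
  if (n_volumes <= 0) stop_ctx("n_volumes must be positive")
  L <- window / repetition_time
  if (window <= 0 || abs(L - round(L)) > 1e-9)
    stop_ctx("window (%.4g s) must be a positive multiple of repetition_time (%.4g s)",
             window, repetition_time)
  L <- as.integer(round(L))
  ev <- event_types()
  G <- matrix(0L, n_volumes, length(ev) * L)
  colnames(G) <- as.vector(vapply(ev, function(e) paste0(e, "_lag", seq_len(L) - 1),
                                  character(L)))
  types <- trial_event_type(events)
  for (i in seq_len(nrow(events))) {
    e_idx <- match(types[i], ev)
    k0 <- ceiling(events$onset[i] / repetition_time - 1e-9)
    for (j in seq_len(L) - 1L) {
      k <- k0 + j
      if (k >= 0 && k < n_volumes) G[k + 1L, (e_idx - 1L) * L + j + 1L] <- 1L
    }
  }
  structure(list(G = G,
                 lag_times = (seq_len(L) - 0.5) * repetition_time,
                 event_types = ev, n_lags = L,
                 repetition_time = repetition_time),
            class = "fir_design")
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf("FIR design: %d volumes x %d columns (%d event types x %d lags, TR %.3g s)\n",
              nrow(x$G), ncol(x$G), length(x$event_types), x$n_lags,
              x$repetition_time))
  invisible(x)
}

#' Report the conditioning of a FIR design
#'
#' Reports the rank and condition number of the cross-product of the design's
#' non-zero columns, lists all-zero columns (event types absent for the
#' subject), and flags elevated collinearity. Fitting downstream always uses
#' the pseudoinverse, so this is diagnostic only.
#'
#' @param design a `fir_design`.
#' @param collinearity_threshold condition number of G'G above which the
#'   design is flagged (default 100; well-jittered schedules sit near 10-20).
#' @return list with rank, condition_number, zero_columns, absent_event_types,
#'   full_rank, collinear.
#' @export
check_design_conditioning <- function(design, collinearity_threshold = 100) {
  G <- design$G
  zero <- colSums(abs(G)) == 0
  absent <- unique(sub("_lag[0-9]+$", "", colnames(G)[zero]))
  Gnz <- G[, !zero, drop = FALSE]
  if (ncol(Gnz) == 0) {
    return(list(rank = 0L, condition_number = NA_real_,
                zero_columns = colnames(G), absent_event_types = absent,
                full_rank = FALSE, collinear = NA))
  }
  d <- svd(Gnz, nu = 0, nv = 0)$d
  tol <- max(dim(Gnz)) * .Machine$double.eps * d[1]
  rank <- sum(d > tol)
  cond <- if (rank < ncol(Gnz)) Inf else (d[1] / d[length(d)])^2
  list(rank = rank,
       condition_number = cond,
       zero_columns = colnames(G)[zero],
       absent_event_types = absent,
       full_rank = rank == ncol(G),
       collinear = is.infinite(cond) || cond > collinearity_threshold)
}
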