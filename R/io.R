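#' Read and write parcellated BOLD time series as TSV
#'
#' Tab-separated table with one column per region (header = region labels)
#' and one row per acquisition.
#'
#' @param bold a `parcellated_bold`.
#' @param path file path.
#' @export
write_bold_tsv <- function(bold, path) {
  df <- as.data.frame(bold$data)
  names(df) <- bold$region_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @param repetition_time TR in seconds to attach on reading.
#' @param cortical optional logical vector of cortical flags.
#' @export
read_bold_tsv <- function(path, repetition_time = 3, cortical = NULL) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  X <- as.matrix(df)
  structure(list(data = X, repetition_time = repetition_time,
                 region_labels = colnames(X),
                 cortical = cortical %||% rep(TRUE, ncol(X))),
            class = "parcellated_bold")
}

#' Write a synthetic cohort to a directory
#'
#' Per-subject time series (`<id>_bold.tsv`) and events (`<id>_events.tsv`),
#' one covariates CSV, and the ground truth as JSON.
#'
#' @param cohort a `cpca_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_bold_tsv(s$bold, file.path(dir, paste0(s$id, "_bold.tsv")))
    write_events(s$events, file.path(dir, paste0(s$id, "_events.tsv")))
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  gt <- cohort$ground_truth
  gt_json <- list(seed = gt$seed, config = gt$config,
                  accuracy = gt$accuracy,
                  amplitudes = gt$amplitudes,
                  spatial_maps = gt$model$spatial_maps,
                  response_curves = as.vector(gt$model$response_curves),
                  response_curves_dim = dim(gt$model$response_curves),
                  behavior_coupling = gt$model$behavior_coupling,
                  noise = list(ar = gt$model$noise_ar, sd = gt$model$noise_sd),
                  group_effects = gt$model$group_effects)
  jsonlite::write_json(gt_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a structural map as CSV (region, value, x, y, z)
#' @param map a `structural_map`.
#' @param path CSV path.
#' @export
write_structural_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
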