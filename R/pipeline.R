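pipeline_defaults <- function() list(
  seed = 1L,
  n_cases = 58L, n_controls = 58L,
  n_trials = 60L, stimulus_duration = 5.5, isi_bounds = c(0.5, 18.5),
  run_duration = 630, repetition_time = 3, window = 18,
  n_regions = 214L, n_cortical = 200L,
  n_planted = 5L, include_global = TRUE,
  n_components = NULL,               # NULL = scree elbow
  standardize = "zscore",
  n_boot = 500L, alpha_threshold = 1e-4,
  n_perm = 500L,
  alpha_select = 0.05,
  peak_convention = "absmax",
  structural_effect_size = 1.5, structural_truth_component = 3L,
  spatial_autocorr_length = 30,
  accuracy_threshold = 0.75,
  robustness = list(accuracy_subset = FALSE, phase_randomized = FALSE),
  out_dir = NULL)

#' Validate and resolve a pipeline configuration
#'
#' Fills defaults, reports every violation at once, and warns (without
#' failing) on unknown keys so configurations stay forward compatible.
#'
#' @param config a named list, or a path to a YAML file.
#' @return resolved configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_ctx("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    warning(sprintf("unknown config key(s) ignored: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- utils::modifyList(defaults, config[intersect(names(config), names(defaults))])
  errors <- character(0)
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  for (key in c("n_cases", "n_controls", "n_trials", "n_boot", "n_perm",
                "n_regions", "n_planted"))
    chk(is.numeric(cfg[[key]]) && cfg[[key]] > 0, paste(key, "must be positive"))
  chk(cfg$repetition_time > 0, "repetition_time must be positive")
  chk(cfg$window > 0 &&
        abs(cfg$window / cfg$repetition_time - round(cfg$window / cfg$repetition_time)) < 1e-9,
      "window must be a positive multiple of repetition_time")
  chk(cfg$accuracy_threshold >= 0 && cfg$accuracy_threshold <= 1,
      "accuracy_threshold must lie in [0, 1]")
  chk(cfg$alpha_threshold > 0 && cfg$alpha_threshold <= 1,
      "alpha_threshold must lie in (0, 1]")
  chk(cfg$alpha_select > 0 && cfg$alpha_select < 1,
      "alpha_select must lie in (0, 1)")
  if (length(errors))
    stop_ctx("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full synthetic-data analysis pipeline
#'
#' simulate -> FIR design -> CPCA -> bootstrap thresholding -> response
#' curves -> growth-model selection per component -> brain-behaviour
#' association -> structural-map alignment, with optional robustness re-runs
#' (high-accuracy subject subset; phase-randomized surrogate null). All stage
#' outputs are written under `out_dir` (when given) with a provenance
#' manifest; the run is a pure function of the resolved configuration.
#'
#' @param config list or YAML path; see [validate_config()].
#' @return invisible list with the resolved config and every stage result.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  model <- default_planted_model(
    n_regions = cfg$n_regions, n_cortical = cfg$n_cortical,
    n_components = cfg$n_planted, include_global = cfg$include_global,
    rng_seed = split_seed(cfg$seed, "model"))
  cohort <- generate_cohort(cfg$n_cases, cfg$n_controls, model,
                            config = cfg[c("n_trials", "stimulus_duration",
                                           "isi_bounds", "run_duration")],
                            rng_seed = split_seed(cfg$seed, "cohort"))
  res <- analyse_cohort(cohort, cfg)
  res$config <- cfg
  res$cohort <- cohort
  if (isTRUE(cfg$robustness$accuracy_subset)) {
    keep <- cohort$covariates$accuracy >= cfg$accuracy_threshold
    message(sprintf("accuracy-subset rerun: %d of %d subjects retained",
                    sum(keep), length(keep)))
    sub <- cohort
    sub$subjects <- cohort$subjects[keep]
    sub$covariates <- cohort$covariates[keep, , drop = FALSE]
    res$accuracy_subset <- analyse_cohort(sub, cfg, stages = "core")
    res$accuracy_subset$n_subjects <- sum(keep)
  }
  if (isTRUE(cfg$robustness$phase_randomized)) {
    surr <- cohort
    for (i in seq_along(surr$subjects))
      surr$subjects[[i]]$bold <- phase_randomize(
        surr$subjects[[i]]$bold, rng_seed = split_seed(cfg$seed, paste0("phase", i)))
    res$phase_randomized <- analyse_cohort(surr, cfg, stages = "core")
  }
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  invisible(res)
}

# Core stages on an existing cohort. stages = "core" skips the structural and
# behavioural stages (used by robustness re-runs, which target the growth
# models).
analyse_cohort <- function(cohort, cfg, stages = c("all", "core")) {
  stages <- match.arg(stages)
  fit <- cpca(cohort, n_components = cfg$n_components,
              standardize = cfg$standardize)
  curves <- response_curves(fit)
  task_components <- setdiff(fit$component_labels, "PC0")
  growth <- lapply(task_components, function(pc) {
    dat <- growth_data(curves, cohort$covariates, pc)
    select_growth_model(dat, alpha = cfg$alpha_select)
  })
  names(growth) <- task_components
  out <- list(fit = fit, curves = curves, growth = growth)
  if (stages == "core") return(out)
  boot <- bootstrap_loadings(fit, n_boot = cfg$n_boot,
                             rng_seed = split_seed(cfg$seed, "boot"))
  maps <- threshold_maps(boot, alpha = cfg$alpha_threshold)
  peaks <- extract_peak_scores(curves, convention = cfg$peak_convention)
  peaks_task <- peaks[peaks$component %in% task_components, , drop = FALSE]
  assoc <- rank_accuracy_regression(peaks_task, cohort$covariates, group = "case")
  structurals <- generate_structural_maps(
    cohort$ground_truth$model,
    truth_component = cfg$structural_truth_component,
    effect_size = cfg$structural_effect_size,
    spatial_autocorr_length = cfg$spatial_autocorr_length,
    rng_seed = split_seed(cfg$seed, "structural"))
  cortical_masks <- lapply(maps, function(m) m[fit$cortical, , drop = FALSE])
  mav <- tryCatch(
    mav_permutation_test(cortical_masks, structurals, n_perm = cfg$n_perm,
                         rng_seed = split_seed(cfg$seed, "mav")),
    error = function(e) { warning(conditionMessage(e), call. = FALSE); NULL })
  c(out, list(boot = boot, maps = maps, peaks = peaks, association = assoc,
              structurals = structurals, mav = mav))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_cohort(res$cohort, file.path(out_dir, "cohort"))
  ld <- data.frame(region = rownames(res$fit$loadings), res$fit$loadings,
                   check.names = FALSE)
  write_tsv(ld, file.path(out_dir, "loadings.tsv"))
  write_tsv(data.frame(component = res$fit$component_labels,
                       variance_explained =
                         res$fit$variance_explained[seq_len(res$fit$n_components)]),
            file.path(out_dir, "variance_explained.tsv"))
  if (!is.null(res$maps))
    for (pc in names(res$maps))
      write_tsv(as.data.frame(res$maps[[pc]]),
                file.path(out_dir, sprintf("map_%s.tsv", pc)))
  write_tsv(as.data.frame(res$curves), file.path(out_dir, "response_curves.tsv"))
  for (pc in names(res$growth)) {
    write_tsv(res$growth[[pc]]$trace,
              file.path(out_dir, sprintf("growth_trace_%s.tsv", pc)))
    write_tsv(res$growth[[pc]]$fit$coefficients,
              file.path(out_dir, sprintf("growth_coefficients_%s.tsv", pc)))
    write_tsv(res$growth[[pc]]$fit$trajectories,
              file.path(out_dir, sprintf("growth_trajectories_%s.tsv", pc)))
  }
  if (!is.null(res$association))
    write_tsv(res$association, file.path(out_dir, "association.tsv"))
  if (!is.null(res$mav)) write_tsv(res$mav, file.path(out_dir, "mav.tsv"))
  if (!is.null(res$structurals))
    for (m in names(res$structurals))
      write_structural_map(res$structurals[[m]],
                           file.path(out_dir, sprintf("structural_%s.csv", m)))
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("taskCPCA")),
    r_version = R.version.string,
    seed = cfg$seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
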