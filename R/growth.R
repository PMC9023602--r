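GROWTH_COVARIATES <- c("age", "sex", "total_brain_volume",
                       "mean_framewise_displacement", "handedness", "group_case")

# Mandatory covariates that are actually estimable on this data set: factor
# covariates with a single observed level are dropped (with a message) rather
# than breaking the fit.
active_covariates <- function(data) {
  keep <- vapply(GROWTH_COVARIATES, function(cc) {
    v <- data[[cc]]
    length(unique(v[!is.na(v)])) >= 2
  }, TRUE)
  if (!all(keep))
    message(sprintf("covariate(s) constant in this sample, dropped: %s",
                    paste(GROWTH_COVARIATES[!keep], collapse = ", ")))
  GROWTH_COVARIATES[keep]
}

#' Assemble growth-model data for one component
#'
#' Long-format modelling table for one component's response-curve estimates
#' over post-event time, restricted to the four response events (the two
#' non-response events are excluded). Post-event time is expressed in seconds
#' at the acquisition-bin midpoints and centered at the window midpoint before
#' polynomials are formed (raw, non-orthogonal powers so coefficients stay
#' interpretable as Time^k effects).
#'
#' @param curves a `response_curve_set`.
#' @param covariates data.frame with subject_id, group, age, sex,
#'   total_brain_volume, mean_framewise_displacement, handedness.
#' @param component component label or index (among retained components).
#' @param max_degree highest time polynomial to precompute (default 5).
#' @return data.frame with score, time, time2..time{max_degree}, threat,
#'   correct, group_case, subject and the mandatory covariates. Rows with an
#'   absent curve entry are dropped; subjects with incomplete covariates are
#'   listwise-deleted with a message.
#' @export
growth_data <- function(curves, covariates, component, max_degree = 5) {
  if (is.numeric(component)) component <- curves$component_labels[component]
  df <- as.data.frame(curves)
  df <- df[df$component == component & df$response_class != "non-response", ,
           drop = FALSE]
  if (!nrow(df)) stop_ctx("no response-event curve estimates for component %s", component)
  cov <- covariates
  need <- c("subject_id", "group", "age", "sex", "total_brain_volume",
            "mean_framewise_displacement", "handedness")
  missing <- setdiff(need, names(cov))
  if (length(missing)) stop_ctx("covariates missing column(s): %s",
                                paste(missing, collapse = ", "))
  complete <- stats::complete.cases(cov[, need])
  if (!all(complete)) {
    message(sprintf("growth_data: %d subject(s) dropped for incomplete covariates",
                    sum(!complete)))
    cov <- cov[complete, , drop = FALSE]
  }
  df <- merge(df, cov, by.x = "subject", by.y = "subject_id")
  mid <- (min(curves$lag_times) + max(curves$lag_times)) / 2
  df$score <- df$estimate
  df$time <- df$lag_time_s - mid
  for (k in 2:max_degree) df[[paste0("time", k)]] <- df$time^k
  df$threat <- as.integer(df$stimulus_class == "threat")
  df$correct <- as.integer(df$response_class == "correct")
  df$group_case <- as.integer(df$group == "case")
  df$sex <- factor(df$sex)
  df$handedness <- factor(df$handedness)
  # z-score continuous nuisance covariates: keeps the design well scaled
  # without touching the time/stimulus/group terms of interest
  for (cc in c("age", "total_brain_volume", "mean_framewise_displacement"))
    df[[cc]] <- as.numeric(scale(df[[cc]]))
  tp <- tapply(df$lag_time_s, interaction(df$subject, df$event_type, drop = TRUE),
               function(v) length(unique(v)))
  if (any(tp < 2)) stop_ctx("fewer than 2 timepoints for some subject-event cells")
  attr(df, "component") <- component
  df
}

#' Fit a multilevel growth model
#'
#' Linear mixed-effects model of component score over post-event time with a
#' subject random intercept (optionally a random time slope), mandatory
#' between-subject covariates (age, sex, total brain volume, mean framewise
#' displacement, handedness, group), and caller-selected fixed terms. When a
#' random time-slope covariance is singular the model is refit without the
#' slope (logged). P-values use Wald t statistics with containment
#' (within/between subject) degrees of freedom.
#'
#' @param data a data.frame from [growth_data()].
#' @param terms character vector of additional fixed terms (e.g. "time",
#'   "time2", "time2:group_case").
#' @param random "intercept", "slope" (intercept + time slope), or "none"
#'   (pooled ordinary least squares; the zero-random-variance reference).
#' @param method "REML" or "ML".
#' @return a `growth_fit`: list with `model`, `coefficients` (estimate, se, t,
#'   df, p per fixed term), `logLik`, `AIC`, `BIC`, `random`, `singular_slope`,
#'   `trajectories` (fitted group x event-type curves at reference covariates),
#'   `formula`.
#' @export
fit_growth_model <- function(data, terms = character(),
                             random = c("intercept", "slope", "none"),
                             method = c("REML", "ML")) {
  random <- match.arg(random); method <- match.arg(method)
  mand <- active_covariates(data)
  rhs <- paste(c(mand, terms), collapse = " + ")
  singular_slope <- FALSE
  if (random == "none") {
    f <- stats::as.formula(paste("score ~", rhs))
    m <- stats::lm(f, data = data)
    sm <- summary(m)$coefficients
    tab <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], df = m$df.residual, p = sm[, 4],
                      row.names = NULL)
    ll <- as.numeric(stats::logLik(m))
    fit <- m
  } else {
    re <- if (random == "slope") "(1 + time | subject)" else "(1 | subject)"
    f <- stats::as.formula(paste("score ~", rhs, "+", re))
    fit <- lme4::lmer(f, data = data, REML = method == "REML",
                      control = lme4::lmerControl(calc.derivs = FALSE))
    if (random == "slope" && lme4::isSingular(fit, tol = 1e-5)) {
      message("singular random time slope; refitting with random intercept only")
      singular_slope <- TRUE
      random <- "intercept"
      f <- stats::as.formula(paste("score ~", rhs, "+ (1 | subject)"))
      fit <- lme4::lmer(f, data = data, REML = method == "REML",
                        control = lme4::lmerControl(calc.derivs = FALSE))
    }
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    tval <- beta / se
    df <- containment_df(fit, data)
    tab <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), t = unname(tval), df = df[names(beta)],
                      p = 2 * stats::pt(-abs(unname(tval)), df[names(beta)]),
                      row.names = NULL)
    ll <- as.numeric(stats::logLik(fit))
  }
  structure(list(model = fit, coefficients = tab, logLik = ll,
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 random = random, singular_slope = singular_slope,
                 method = method, terms = terms, formula = f,
                 trajectories = fitted_trajectories(fit, data),
                 component = attr(data, "component")),
            class = "growth_fit")
}

# Containment degrees of freedom: fixed-effect columns that vary within
# subjects are tested against the within-subject stratum, between-subject
# columns against the subject stratum (the convention behind df values like
# 2200 vs 96 at study scale).
containment_df <- function(fit, data) {
  X <- stats::model.matrix(fit)
  subj <- data$subject
  if (length(subj) != nrow(X))
    stop_ctx("internal: model rows (%d) do not match data rows (%d)",
             nrow(X), length(subj))
  within <- apply(X, 2, function(col)
    any(tapply(col, subj, function(v) max(v) - min(v)) > 1e-10))
  n_obs <- nrow(X); n_subj <- length(unique(subj))
  p_within <- sum(within)
  p_between <- sum(!within) - 1  # exclude intercept
  df <- ifelse(within, n_obs - n_subj - p_within,
               max(n_subj - p_between - 1, 1))
  stats::setNames(df, colnames(X))
}

# Fitted trajectories for the prototypical subject of each group x event type.
fitted_trajectories <- function(fit, data) {
  times <- sort(unique(data$time))
  grid <- expand.grid(time = times, threat = 0:1, correct = 0:1,
                      group_case = 0:1, KEEP.OUT.ATTRS = FALSE)
  for (k in grep("^time[0-9]+$", names(data), value = TRUE))
    grid[[k]] <- grid$time^as.integer(sub("time", "", k))
  grid$age <- mean(data$age)
  grid$total_brain_volume <- mean(data$total_brain_volume)
  grid$mean_framewise_displacement <- mean(data$mean_framewise_displacement)
  grid$sex <- factor(levels(data$sex)[1], levels = levels(data$sex))
  grid$handedness <- factor(levels(data$handedness)[1],
                            levels = levels(data$handedness))
  grid$fitted <- if (inherits(fit, "merMod"))
    stats::predict(fit, newdata = grid, re.form = NA)
  else stats::predict(fit, newdata = grid)
  grid$event_type <- paste(ifelse(grid$threat == 1, "threat", "non-threat"),
                           ifelse(grid$correct == 1, "correct", "incorrect"),
                           sep = "_")
  grid$group <- ifelse(grid$group_case == 1, "case", "control")
  grid[, c("group", "event_type", "time", "fitted")]
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat(sprintf("multilevel growth model (%s, random: %s)%s\n", x$method, x$random,
              if (!is.null(x$component)) paste0(" for component ", x$component) else ""))
  cat(sprintf("logLik %.2f, AIC %.2f, BIC %.2f\n", x$logLik, x$AIC, x$BIC))
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) object

#' Default candidate ladder for growth-model selection
#'
#' Forward-stepwise candidates in hierarchy-respecting order: time polynomials
#' in increasing degree, then stimulus/response terms and their time
#' interactions, then group interactions. Each entry lists the terms that must
#' already be selected before it may be tested.
#'
#' @param max_degree highest time polynomial (default 5).
#' @return list of entries `list(term =, requires =)`.
#' @export
default_growth_ladder <- function(max_degree = 5) {
  tv <- c("time", paste0("time", 2:max_degree))
  ladder <- list(list(term = "time", requires = character(0)))
  for (k in 2:max_degree)
    ladder <- c(ladder, list(list(term = tv[k], requires = tv[k - 1])))
  ladder <- c(ladder,
              list(list(term = "threat", requires = character(0)),
                   list(term = "correct", requires = character(0)),
                   list(term = "threat:correct", requires = c("threat", "correct"))))
  for (k in seq_len(max_degree)) {
    ladder <- c(ladder,
                list(list(term = paste0(tv[k], ":threat"), requires = c(tv[k], "threat")),
                     list(term = paste0(tv[k], ":correct"), requires = c(tv[k], "correct"))))
  }
  for (k in seq_len(max_degree)) {
    ladder <- c(ladder, list(list(term = paste0(tv[k], ":group_case"),
                                  requires = tv[k])))
  }
  for (k in seq_len(max_degree)) {
    ladder <- c(ladder,
                list(list(term = paste0(tv[k], ":threat:group_case"),
                          requires = c(paste0(tv[k], ":threat"),
                                       paste0(tv[k], ":group_case"))),
                     list(term = paste0(tv[k], ":correct:group_case"),
                          requires = c(paste0(tv[k], ":correct"),
                                       paste0(tv[k], ":group_case")))))
  }
  ladder
}

#' Simulate growth-model data from known fixed effects
#'
#' Generates a long-format modelling table (as produced by [growth_data()])
#' directly from a specified linear mixed model: four response events x six
#' lags per subject, a subject random intercept, optional random time slope,
#' Gaussian residual noise, and simple synthetic covariates. Used for
#' selection-consistency and coverage experiments where the generating model
#' must be known exactly.
#'
#' @param n_subjects total subjects (half assigned to the case group).
#' @param effects named numeric vector of true fixed effects on model terms
#'   (e.g. c(time = 0.05, time2 = -0.03, "time2:group_case" = 0.02)); terms
#'   must be formable from time polynomials, threat, correct and group_case.
#' @param random_intercept_sd,random_slope_sd,residual_sd variance components.
#' @param lag_times acquisition midpoints in seconds (default 1.5..16.5).
#' @param rng_seed integer seed.
#' @return data.frame suitable for [fit_growth_model()] / [select_growth_model()].
#' @export
simulate_growth_data <- function(n_subjects = 40, effects = c(time = 0.05),
                                 random_intercept_sd = 0.3,
                                 random_slope_sd = 0,
                                 residual_sd = 0.5,
                                 lag_times = (1:6 - 0.5) * 3,
                                 rng_seed = 1L) {
  ev <- event_types(response_only = TRUE)
  mid <- (min(lag_times) + max(lag_times)) / 2
  df <- expand.grid(subject = sprintf("sub-%03d", seq_len(n_subjects)),
                    event_type = ev, lag_time_s = lag_times,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$time <- df$lag_time_s - mid
  for (k in 2:5) df[[paste0("time", k)]] <- df$time^k
  df$threat <- as.integer(grepl("^threat", df$event_type))
  df$correct <- as.integer(grepl("_correct$", df$event_type))
  with_seed(rng_seed, {
    subj <- sprintf("sub-%03d", seq_len(n_subjects))
    info <- data.frame(subject = subj,
                       group_case = rep(c(1L, 0L), length.out = n_subjects),
                       age = stats::rnorm(n_subjects, 20, 4),
                       sex = factor(sample(c("M", "F"), n_subjects, replace = TRUE)),
                       total_brain_volume = stats::rnorm(n_subjects, 1165, 120),
                       mean_framewise_displacement = pmax(0.01, stats::rnorm(n_subjects, 0.1, 0.04)),
                       handedness = factor(sample(c("right", "left"), n_subjects,
                                                  replace = TRUE, prob = c(0.9, 0.1))),
                       u0 = stats::rnorm(n_subjects, 0, random_intercept_sd),
                       u1 = stats::rnorm(n_subjects, 0, random_slope_sd))
    df <- merge(df, info, by = "subject")
    X <- stats::model.matrix(
      stats::as.formula(paste("~ 0 +", paste(names(effects), collapse = " + "))), df)
    eta <- as.numeric(X[, names(effects), drop = FALSE] %*% effects)
    df$score <- eta + df$u0 + df$u1 * df$time +
      stats::rnorm(nrow(df), 0, residual_sd)
  })
  df$group <- ifelse(df$group_case == 1, "case", "control")
  df$u0 <- df$u1 <- NULL
  for (cc in c("age", "total_brain_volume", "mean_framewise_displacement"))
    df[[cc]] <- as.numeric(scale(df[[cc]]))
  df
}

#' Partially supervised growth-model selection
#'
#' Forward stepwise selection over a hierarchy-respecting candidate ladder:
#' a candidate is tested only once its prerequisites are selected, and is
#' admitted when the maximum-likelihood likelihood-ratio test improves fit at
#' `alpha`. Mandatory covariates are never dropped. After fixed-term
#' selection, a random time slope is tested by LRT and kept unless singular.
#' The final model is refit by REML.
#'
#' @param data a data.frame from [growth_data()].
#' @param ladder candidate list from [default_growth_ladder()].
#' @param alpha selection level (default 0.05).
#' @param test_random_slope logical (default TRUE).
#' @return a `growth_selection`: list with `terms`, `fit` (REML `growth_fit`),
#'   `random`, and `trace` (term, tested, lrt, df, p, added).
#' @export
select_growth_model <- function(data, ladder = default_growth_ladder(),
                                alpha = 0.05, test_random_slope = TRUE) {
  if (!length(ladder)) stop_ctx("candidate ladder is empty")
  seen <- character(0)
  for (entry in ladder) {
    if (!all(entry$requires %in% c(seen, GROWTH_COVARIATES)))
      stop_ctx("invalid ladder: '%s' requires '%s' which appears later or never",
               entry$term, setdiff(entry$requires, seen)[1])
    seen <- c(seen, entry$term)
  }
  mand <- active_covariates(data)
  ml_fit <- function(terms) {
    f <- stats::as.formula(paste("score ~",
                                 paste(c(mand, terms), collapse = " + "),
                                 "+ (1 | subject)"))
    lme4::lmer(f, data = data, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE))
  }
  selected <- character(0)
  current <- ml_fit(selected)
  trace <- list()
  for (entry in ladder) {
    eligible <- all(entry$requires %in% c(selected, GROWTH_COVARIATES))
    if (!eligible) {
      trace[[length(trace) + 1]] <- data.frame(term = entry$term, tested = FALSE,
                                               lrt = NA, df = NA, p = NA, added = FALSE)
      next
    }
    cand <- ml_fit(c(selected, entry$term))
    an <- stats::anova(current, cand)
    lrt <- an$Chisq[2]; dfd <- an$Df[2]; p <- an$`Pr(>Chisq)`[2]
    add <- is.finite(p) && p < alpha
    trace[[length(trace) + 1]] <- data.frame(term = entry$term, tested = TRUE,
                                             lrt = lrt, df = dfd, p = p, added = add)
    if (add) { selected <- c(selected, entry$term); current <- cand }
  }
  random <- "intercept"
  if (test_random_slope && "time" %in% selected) {
    f_sl <- stats::as.formula(paste("score ~",
                                    paste(c(mand, selected), collapse = " + "),
                                    "+ (1 + time | subject)"))
    m_sl <- tryCatch(lme4::lmer(f_sl, data = data, REML = FALSE,
                                control = lme4::lmerControl(calc.derivs = FALSE)),
                     error = function(e) NULL)
    if (!is.null(m_sl) && !lme4::isSingular(m_sl, tol = 1e-5)) {
      an <- stats::anova(current, m_sl)
      if (is.finite(an$`Pr(>Chisq)`[2]) && an$`Pr(>Chisq)`[2] < alpha)
        random <- "slope"
    }
  }
  fit <- fit_growth_model(data, terms = selected, random = random, method = "REML")
  structure(list(terms = selected, fit = fit, random = random,
                 trace = do.call(rbind, trace), alpha = alpha),
            class = "growth_selection")
}

#' @export
print.growth_selection <- function(x, ...) {
  cat(sprintf("growth-model selection (alpha = %g): %d term(s) selected\n",
              x$alpha, length(x$terms)))
  if (length(x$terms)) cat("  ", paste(x$terms, collapse = ", "), "\n")
  cat(sprintf("random structure: %s\n", x$random))
  invisible(x)
}
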