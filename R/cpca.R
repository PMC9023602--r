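#' Extract task-related variance by FIR regression
#'
#' Regresses each region's (optionally standardized) time series on the FIR
#' design and returns the predicted (task-related) matrix and the residual.
#' The least-squares operator is the Moore-Penrose pseudoinverse, so
#' rank-deficient designs (absent event types, pathological schedules) are
#' handled without failure; deficiency is recorded.
#'
#' @param bold a `parcellated_bold` or a volumes x regions matrix.
#' @param design a `fir_design` with matching volume count.
#' @param standardize per-region preprocessing before regression: "zscore"
#'   (center and scale), "center", or "none".
#' @return list with `predicted` (volumes x regions), `residual`,
#'   `coefficients` (design columns x regions), `standardization` (means, sds,
#'   method), `rank` and `rank_deficient`.
#' @export
extract_task_variance <- function(bold, design,
                                  standardize = c("zscore", "center", "none")) {
  standardize <- match.arg(standardize)
  X <- if (inherits(bold, "parcellated_bold")) bold$data else as.matrix(bold)
  G <- design$G
  if (nrow(X) != nrow(G))
    stop_ctx("volume mismatch: BOLD has %d volumes, design has %d rows",
             nrow(X), nrow(G))
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  Z <- switch(standardize,
              zscore = sweep(sweep(X, 2, mu), 2, ifelse(sds > 0, sds, 1), `/`),
              center = sweep(X, 2, mu),
              none = X)
  sv <- svd(G)
  tol <- max(dim(G)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  rank <- sum(pos)
  # B = G+ Z via the thin SVD
  B <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% Z) / sv$d[pos])
  predicted <- G %*% B
  list(predicted = predicted, residual = Z - predicted, coefficients = B,
       standardization = list(method = standardize, means = mu, sds = sds),
       rank = rank, rank_deficient = rank < ncol(G))
}

#' Constrained principal component analysis of a cohort
#'
#' The core estimator: for every subject the BOLD matrix is standardized and
#' regressed on that subject's FIR design; the per-subject predicted
#' (task-related) matrices are stacked over subjects and decomposed by one
#' singular value decomposition, giving group-level spatial loadings (right
#' singular vectors) with subject-level temporal scores (the corresponding
#' rows of U D). Variance accounted for is `d_k^2 / sum d_j^2` over the
#' task-related variance. Each loading column is sign-fixed so its
#' largest-|value| entry is positive. A near-uniform-sign component, if
#' present among the retained set, is flagged as the global component (PC0)
#' and the remaining components are re-indexed PC1..PC(K-1).
#'
#' @param cohort a `cpca_cohort`, or a list of `parcellated_bold` objects.
#' @param designs list of `fir_design`s, one per subject (taken from the
#'   cohort when omitted).
#' @param n_components number of components to retain; NULL selects the elbow
#'   of the cumulative scree curve via [choose_n_components()].
#' @param standardize passed to [extract_task_variance()].
#' @param global_threshold same-sign fraction above which a component is
#'   flagged global (default 0.90); set > 1 to disable.
#' @param keep_predicted keep per-subject predicted matrices in the fit
#'   (needed for [bootstrap_loadings()]; default TRUE).
#' @return an object of class `cpca`; see Details.
#' @details The fit contains: `loadings` (regions x retained components, in
#'   variance order, sign-fixed), `scores` (per-subject volumes x retained
#'   components blocks of U D), `d` (all singular values),
#'   `variance_explained` (all components), `n_components`,
#'   `global_component` (index among retained, or NA), `component_labels`
#'   (PC0/PC1/... after re-indexing), `rank_deficient_subjects`,
#'   `standardization`, `region_labels`.
#' @export
cpca <- function(cohort, designs = NULL, n_components = NULL,
                 standardize = c("zscore", "center", "none"),
                 global_threshold = 0.90, keep_predicted = TRUE) {
  standardize <- match.arg(standardize)
  if (inherits(cohort, "cpca_cohort")) {
    bolds <- lapply(cohort$subjects, `[[`, "bold")
    designs <- designs %||% lapply(cohort$subjects, `[[`, "design")
    ids <- vapply(cohort$subjects, `[[`, "", "id")
  } else {
    bolds <- cohort
    ids <- names(bolds) %||% sprintf("sub-%03d", seq_along(bolds))
  }
  if (is.null(designs) || length(designs) != length(bolds))
    stop_ctx("one fir_design per subject is required")
  R <- ncol(if (inherits(bolds[[1]], "parcellated_bold")) bolds[[1]]$data else bolds[[1]])
  C <- matrix(0, R, R)
  predicted <- vector("list", length(bolds))
  rank_def <- logical(length(bolds))
  total_rows <- 0
  for (i in seq_along(bolds)) {
    tv <- extract_task_variance(bolds[[i]], designs[[i]], standardize)
    predicted[[i]] <- tv$predicted
    rank_def[i] <- tv$rank_deficient
    C <- C + crossprod(tv$predicted)
    total_rows <- total_rows + nrow(tv$predicted)
  }
  if (any(rank_def))
    warning(sprintf("rank-deficient FIR design for %d subject(s); pseudoinverse used",
                    sum(rank_def)), call. = FALSE)
  eg <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  d <- sqrt(lambda)
  ve <- if (sum(lambda) > 0) lambda / sum(lambda) else lambda
  V <- eg$vectors
  # deterministic sign: largest-|loading| entry positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  scree <- choose_n_components(ve)
  if (is.null(n_components)) n_components <- scree$retained
  if (n_components > min(R, total_rows))
    stop_ctx("n_components (%d) exceeds the rank bound min(%d regions, %d rows)",
             n_components, R, total_rows)
  Vr <- V[, seq_len(n_components), drop = FALSE]
  scores <- lapply(predicted, function(P) P %*% Vr)
  names(scores) <- ids
  rl <- if (inherits(bolds[[1]], "parcellated_bold")) bolds[[1]]$region_labels
        else sprintf("region_%03d", seq_len(R))
  rownames(Vr) <- rl
  fit <- structure(list(loadings = Vr, scores = scores, d = d,
                        variance_explained = ve, n_components = n_components,
                        scree = scree,
                        global_component = NA_integer_,
                        component_labels = paste0("PC", seq_len(n_components)),
                        rank_deficient_subjects = ids[rank_def],
                        standardization = standardize,
                        region_labels = rl,
                        designs = designs,
                        cortical = if (inherits(bolds[[1]], "parcellated_bold"))
                          bolds[[1]]$cortical else rep(TRUE, R),
                        predicted = if (keep_predicted) predicted else NULL,
                        subject_ids = ids,
                        call = match.call()),
                   class = "cpca")
  g <- identify_global_component(fit, threshold = global_threshold)
  if (!is.na(g)) {
    fit$global_component <- g
    labels <- character(n_components)
    labels[g] <- "PC0"
    labels[-g] <- paste0("PC", seq_len(n_components - 1))
    fit$component_labels <- labels
  }
  colnames(fit$loadings) <- fit$component_labels
  fit$scores <- lapply(fit$scores, function(S) { colnames(S) <- fit$component_labels; S })
  fit
}

#' Identify a global signal component
#'
#' Among the retained components, the one whose loadings have the highest
#' same-sign fraction is flagged as a global signal fluctuation when that
#' fraction exceeds `threshold`; downstream the flagged component is labelled
#' PC0 and the remaining components re-indexed PC1..PC(K-1).
#'
#' @param fit a `cpca` fit (or a regions x components loadings matrix).
#' @param threshold same-sign fraction required (default 0.90).
#' @return integer index of the global component among the retained set, or
#'   NA when none exceeds the threshold.
#' @export
identify_global_component <- function(fit, threshold = 0.90) {
  V <- if (inherits(fit, "cpca")) fit$loadings else as.matrix(fit)
  frac <- apply(V, 2, function(v) {
    nz <- v[v != 0]
    if (!length(nz)) return(0)
    max(mean(nz > 0), mean(nz < 0))
  })
  if (max(frac) > threshold) which.max(frac) else NA_integer_
}

#' Choose the number of components by the scree elbow
#'
#' Computes the elbow of the cumulative variance-explained curve by the
#' maximum-distance-to-chord criterion: both axes are normalized to [0, 1],
#' and the retained count is the point of maximal perpendicular distance to
#' the chord joining the first and last points of the cumulative curve.
#'
#' @param variance_explained non-increasing vector of variance fractions.
#' @return list with `retained` (elbow index), `distances`, and `cumulative`
#'   (cumulative variance fractions).
#' @export
choose_n_components <- function(variance_explained) {
  ve <- variance_explained
  if (any(diff(ve) > 1e-8))
    stop_ctx("variance_explained must be non-increasing")
  m <- length(ve)
  if (m < 3) return(list(retained = m, distances = rep(0, m), cumulative = cumsum(ve)))
  cy <- cumsum(ve)
  x <- (seq_len(m) - 1) / (m - 1)
  span <- cy[m] - cy[1]
  y <- if (span > 0) (cy - cy[1]) / span else rep(0, m)
  dist <- abs(y - x) / sqrt(2)
  list(retained = which.max(dist), distances = dist, cumulative = cy)
}

#' @export
print.cpca <- function(x, ...) {
  cat(sprintf("CPCA fit: %d subjects, %d regions, %d retained components\n",
              length(x$scores), nrow(x$loadings), x$n_components))
  cum <- sum(x$variance_explained[seq_len(x$n_components)])
  cat(sprintf("retained components explain %.1f%% of task-related variance\n",
              100 * cum))
  if (!is.na(x$global_component))
    cat(sprintf("global component flagged: original index %d (labelled PC0, %.1f%% of variance)\n",
                x$global_component, 100 * x$variance_explained[x$global_component]))
  invisible(x)
}

#' @export
summary.cpca <- function(object, ...) {
  k <- object$n_components
  tab <- data.frame(component = object$component_labels,
                    variance_explained = object$variance_explained[seq_len(k)],
                    cumulative = cumsum(object$variance_explained[seq_len(k)]))
  structure(list(table = tab, n_subjects = length(object$scores),
                 n_regions = nrow(object$loadings),
                 global_component = object$global_component,
                 standardization = object$standardization),
            class = "summary.cpca")
}

#' @export
print.summary.cpca <- function(x, ...) {
  cat(sprintf("CPCA solution (%d subjects, %d regions, standardization: %s)\n",
              x$n_subjects, x$n_regions, x$standardization))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.cpca <- function(object, ...) object$loadings

#' @export
plot.cpca <- function(x, ...) screeplot(x, ...)

#' @importFrom stats screeplot
#' @export
screeplot.cpca <- function(x, npcs = min(20, length(x$variance_explained)), ...) {
  ve <- x$variance_explained[seq_len(npcs)]
  graphics::plot(seq_len(npcs), ve, type = "b", xlab = "component",
                 ylab = "fraction of task-related variance", ...)
  graphics::abline(v = x$n_components + 0.5, lty = 2)
  invisible(x)
}
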