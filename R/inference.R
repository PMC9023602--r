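#' Bootstrap significance of CPCA spatial loadings
#'
#' Subjects are resampled with replacement; the group decomposition is refit
#' on each replicate; replicate components are aligned to the reference
#' solution by greedy maximal-|correlation| matching with sign flipping; and
#' per-region significance is assessed by the normal approximation
#' `z = loading / bootstrap SE` (two-sided), which supports fixed analytic
#' thresholds such as p < 1e-4 that empirical percentiles cannot reach at
#' feasible replicate counts.
#'
#' @param fit a `cpca` fit created with `keep_predicted = TRUE`.
#' @param n_boot number of bootstrap replicates (default 500, minimum 100).
#' @param rng_seed integer seed.
#' @return a `cpca_boot`: list with `se`, `z`, `p` (each regions x retained
#'   components), `n_boot`, `n_failed`.
#' @export
bootstrap_loadings <- function(fit, n_boot = 500, rng_seed = 1L) {
  if (!inherits(fit, "cpca") || is.null(fit$predicted))
    stop_ctx("bootstrap_loadings needs a cpca fit with keep_predicted = TRUE")
  if (n_boot < 100) stop_ctx("n_boot must be >= 100")
  K <- fit$n_components
  Vref <- fit$loadings
  R <- nrow(Vref); n <- length(fit$predicted)
  acc <- array(NA_real_, dim = c(R, K, n_boot))
  failed <- 0
  with_seed(rng_seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      Vb <- tryCatch({
        C <- matrix(0, R, R)
        for (i in idx) C <- C + crossprod(fit$predicted[[i]])
        eigen(C, symmetric = TRUE)$vectors[, seq_len(K), drop = FALSE]
      }, error = function(e) NULL)
      if (is.null(Vb)) { failed <- failed + 1; next }
      m <- align_loadings(Vb, Vref)
      acc[, , b] <- m
    }
  })
  if (failed > 0.10 * n_boot)
    stop_ctx("bootstrap failed for %d of %d replicates", failed, n_boot)
  if (failed > 0)
    message(sprintf("bootstrap: %d of %d replicates dropped", failed, n_boot))
  se <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
  z <- Vref / ifelse(se > 0, se, NA)
  p <- 2 * stats::pnorm(-abs(z))
  dimnames(se) <- dimnames(z) <- dimnames(p) <- dimnames(Vref)
  structure(list(se = se, z = z, p = p, n_boot = n_boot, n_failed = failed,
                 loadings = Vref),
            class = "cpca_boot")
}

# Align replicate loading columns to a reference by greedy |correlation|
# matching with sign flips; returns the re-ordered, re-signed columns.
align_loadings <- function(Vb, Vref) {
  K <- ncol(Vref)
  S <- suppressWarnings(stats::cor(Vref, Vb))
  S[!is.finite(S)] <- 0
  A <- abs(S)
  out <- matrix(NA_real_, nrow(Vref), K)
  used <- logical(ncol(Vb))
  remaining <- seq_len(K)
  while (length(remaining)) {
    A2 <- A
    A2[, used] <- -Inf
    A2[setdiff(seq_len(K), remaining), ] <- -Inf
    idx <- which(A2 == max(A2), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    s <- sign(S[idx[1], idx[2]]); if (s == 0) s <- 1
    out[, idx[1]] <- s * Vb[, idx[2]]
    used[idx[2]] <- TRUE
    remaining <- setdiff(remaining, idx[1])
  }
  out
}

#' Threshold a spatial loading map by bootstrap p-values
#'
#' @param loadings numeric vector of regional loadings.
#' @param p_values numeric vector of the same length.
#' @param alpha threshold (default 1e-4); mask is `p < alpha`.
#' @param se,z optional bootstrap SE and z-ratio to carry along.
#' @param region_labels optional region names.
#' @return a `thresholded_map` data.frame (region, loading, se, z, p, mask)
#'   with attribute `alpha`. Sub-threshold loadings are retained in the table;
#'   `thresholded_values()` returns the rendered map with them set to zero.
#' @export
threshold_map <- function(loadings, p_values, alpha = 1e-4, se = NULL, z = NULL,
                          region_labels = NULL) {
  if (length(loadings) != length(p_values))
    stop_ctx("loadings and p_values lengths differ (%d vs %d)",
             length(loadings), length(p_values))
  out <- data.frame(
    region = region_labels %||% names(loadings) %||%
      sprintf("region_%03d", seq_along(loadings)),
    loading = as.numeric(loadings),
    se = if (is.null(se)) NA_real_ else as.numeric(se),
    z = if (is.null(z)) NA_real_ else as.numeric(z),
    p = as.numeric(p_values),
    mask = as.numeric(p_values) < alpha,
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("thresholded_map", "data.frame")
  out
}

#' @rdname threshold_map
#' @param map a `thresholded_map`.
#' @export
thresholded_values <- function(map) ifelse(map$mask, map$loading, 0)

#' Threshold every retained component of a bootstrap result
#' @param boot a `cpca_boot`.
#' @param alpha significance threshold (default 1e-4).
#' @return named list of `thresholded_map`s, one per component.
#' @export
threshold_maps <- function(boot, alpha = 1e-4) {
  stats::setNames(lapply(seq_len(ncol(boot$p)), function(k)
    threshold_map(boot$loadings[, k], boot$p[, k], alpha,
                  se = boot$se[, k], z = boot$z[, k],
                  region_labels = rownames(boot$loadings))),
    colnames(boot$loadings))
}

#' Phase-randomized surrogate of a parcellated BOLD run
#'
#' Multiplies the positive-frequency Fourier coefficients of every region's
#' series by random unit phases that are shared across regions, and inverts.
#' Each region's power spectrum (hence mean and autocovariance) is preserved
#' exactly, as are all cross-spectral magnitudes and the lag-0 cross-covariance
#' structure; event-locking to the task is destroyed. This is the
#' stimulus-independence null used for whole-pipeline calibration.
#'
#' @param bold a `parcellated_bold` or volumes x regions matrix (>= 8 volumes).
#' @param rng_seed integer seed.
#' @return surrogate of the same class and dimensions.
#' @export
phase_randomize <- function(bold, rng_seed = 1L) {
  is_pb <- inherits(bold, "parcellated_bold")
  X <- if (is_pb) bold$data else as.matrix(bold)
  n <- nrow(X)
  if (n < 8) stop_ctx("phase randomization needs >= 8 volumes, got %d", n)
  F <- stats::mvfft(X)
  half <- floor((n - 1) / 2)
  with_seed(rng_seed, {
    theta <- stats::runif(half, 0, 2 * pi)
    nyq_sign <- sample(c(-1, 1), 1)
  })
  rot <- exp(1i * theta)
  if (half > 0) {
    F[1 + seq_len(half), ] <- F[1 + seq_len(half), , drop = FALSE] * rot
    F[n + 1 - seq_len(half), ] <- F[n + 1 - seq_len(half), , drop = FALSE] * Conj(rot)
  }
  if (n %% 2 == 0) F[n / 2 + 1, ] <- F[n / 2 + 1, ] * nyq_sign
  Y <- Re(stats::mvfft(F, inverse = TRUE)) / n
  dimnames(Y) <- dimnames(X)
  if (is_pb) { out <- bold; out$data <- Y; out } else Y
}
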