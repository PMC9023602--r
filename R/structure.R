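#' Construct a regional structural difference map
#'
#' @param region region labels (cortical regions only).
#' @param value signed difference value per region.
#' @param x,y,z parcel centroid coordinates in mm (required; surrogate
#'   generation needs them).
#' @param metric metric label (e.g. "cortical_thickness").
#' @return a `structural_map` data.frame.
#' @export
structural_map <- function(region, value, x, y, z, metric = "structural") {
  n <- length(region)
  stopifnot(length(value) == n, length(x) == n, length(y) == n, length(z) == n)
  if (anyNA(c(x, y, z))) stop_ctx("centroid coordinates must be complete")
  structure(data.frame(region = region, value = value, x = x, y = y, z = z,
                       stringsAsFactors = FALSE),
            metric = metric, class = c("structural_map", "data.frame"))
}

#' Read a structural map from CSV (region, value, x, y, z)
#' @param path CSV path.
#' @param metric metric label.
#' @export
read_structural_map <- function(path, metric = "structural") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structural_map(df$region, df$value, df$x, df$y, df$z, metric)
}

#' Mean absolute value of structural change within a component's mask
#'
#' MAV = mean of |difference value| over the suprathreshold cortical regions
#' of a thresholded component map; it captures the total extent of structural
#' differences (increases and decreases alike) within activated or
#' deactivated regions.
#'
#' @param structural a `structural_map` (cortical regions).
#' @param mask a `thresholded_map`, or a logical vector over the structural
#'   map's regions, or a character vector of suprathreshold region names.
#' @return the MAV (non-negative scalar).
#' @export
compute_mav <- function(structural, mask) {
  sel <- if (inherits(mask, "thresholded_map")) {
    structural$region %in% mask$region[mask$mask]
  } else if (is.logical(mask)) {
    if (length(mask) != nrow(structural))
      stop_ctx("logical mask length (%d) must match structural regions (%d)",
               length(mask), nrow(structural))
    mask
  } else structural$region %in% mask
  if (!any(sel)) stop_ctx("no suprathreshold cortical regions")
  mean(abs(structural$value[sel]))
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Variogram-matched permutation surrogates: the map's values are randomly
#' permuted across regions, smoothed with an exponential kernel over
#' inter-centroid distances whose bandwidth is fit so the surrogates'
#' empirical variogram matches the original map's at short range, and finally
#' rank-remapped onto the original value multiset. Each surrogate is therefore
#' a reassignment of the observed values (the multiset is preserved exactly)
#' with approximately the observed spatial covariance.
#'
#' @param structural a `structural_map` with centroid coordinates.
#' @param n_perm number of surrogates (>= 100).
#' @param rng_seed integer seed.
#' @param bandwidths candidate kernel length scales (mm) searched during the
#'   variogram fit; 0 means unsmoothed permutation.
#' @return regions x n_perm matrix of surrogate values.
#' @export
generate_surrogate_maps <- function(structural, n_perm = 500, rng_seed = 1L,
                                    bandwidths = c(0, 5, 10, 20, 30, 50, 80)) {
  if (n_perm < 100) stop_ctx("n_perm must be >= 100")
  v <- structural$value
  R <- length(v)
  D <- as.matrix(stats::dist(structural[, c("x", "y", "z")]))
  if (any(D[upper.tri(D)] < 1e-9)) stop_ctx("duplicate parcel centroids")
  sorted <- sort(v)
  vg_obs <- variogram_profile(v, D)
  with_seed(rng_seed, {
    # fit the bandwidth on a small pilot set of permutations
    n_pilot <- 20
    pilot <- matrix(0, R, n_pilot)
    for (j in seq_len(n_pilot)) pilot[, j] <- v[sample.int(R)]
    score <- vapply(bandwidths, function(bw) {
      S <- smooth_remap(pilot, D, bw, sorted)
      vg <- rowMeans(apply(S, 2, variogram_profile, D = D))
      sum((vg - vg_obs)^2)
    }, 0)
    bw <- bandwidths[which.min(score)]
    P <- matrix(0, R, n_perm)
    for (j in seq_len(n_perm)) P[, j] <- v[sample.int(R)]
    out <- smooth_remap(P, D, bw, sorted)
  })
  rownames(out) <- structural$region
  out
}

# Smooth permuted fields with an exponential kernel and remap ranks onto the
# original value multiset. bw = 0 leaves the permutation untouched.
smooth_remap <- function(P, D, bw, sorted_values) {
  S <- if (bw > 0) exp(-D / bw) %*% P else P
  apply(S, 2, function(col) sorted_values[rank(col, ties.method = "first")])
}

# Binned semivariance over the shortest-distance half of region pairs.
variogram_profile <- function(v, D, n_bins = 10) {
  ut <- upper.tri(D)
  d <- D[ut]
  keep <- d <= stats::median(d)
  g <- 0.5 * (outer(v, v, `-`)^2)[ut][keep]
  bins <- cut(d[keep], breaks = stats::quantile(d[keep], probs = seq(0, 1, length.out = n_bins + 1)),
              include.lowest = TRUE)
  as.numeric(tapply(g, bins, mean))
}

#' MAV permutation test across components and structural metrics
#'
#' For every (component mask, structural metric) cell: the observed MAV is
#' compared with the null distribution of MAVs computed on
#' spatial-autocorrelation-preserving surrogates of the structural map, with
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`. Benjamini-Hochberg FDR is
#' applied over the full family (six components x two metrics = 12 cells at
#' study scale).
#'
#' @param masks named list of `thresholded_map`s (one per component).
#' @param structurals named list of `structural_map`s (one per metric).
#' @param n_perm number of surrogates per metric (default 500).
#' @param rng_seed integer seed.
#' @return a `mav_result` data.frame: component, metric, mav, p, q, n_perm;
#'   attribute `null` holds the per-cell null distributions.
#' @export
mav_permutation_test <- function(masks, structurals, n_perm = 500, rng_seed = 1L) {
  stopifnot(length(masks) >= 1, length(structurals) >= 1)
  comp_names <- names(masks) %||% paste0("PC", seq_along(masks) - 1)
  met_names <- names(structurals) %||% paste0("metric", seq_along(structurals))
  nulls <- list()
  rows <- list()
  for (m in seq_along(structurals)) {
    sm <- structurals[[m]]
    sur <- generate_surrogate_maps(sm, n_perm = n_perm,
                                   rng_seed = split_seed(rng_seed, met_names[m]))
    for (k in seq_along(masks)) {
      sel <- sm$region %in% masks[[k]]$region[masks[[k]]$mask]
      if (!any(sel)) stop_ctx("no suprathreshold cortical regions for %s", comp_names[k])
      obs <- mean(abs(sm$value[sel]))
      null <- colMeans(abs(sur[sel, , drop = FALSE]))
      p <- (1 + sum(null >= obs)) / (n_perm + 1)
      rows[[length(rows) + 1]] <- data.frame(component = comp_names[k],
                                             metric = met_names[m],
                                             mav = obs, p = p, n_perm = n_perm,
                                             stringsAsFactors = FALSE)
      nulls[[paste(comp_names[k], met_names[m], sep = ".")]] <- null
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- fdr_adjust(out$p)
  attr(out, "null") <- nulls
  class(out) <- c("mav_result", "data.frame")
  out
}
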