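#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library functions never clobber user randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed from a master seed and a stage label.
# Kept below 2^31 so it is always a valid R integer seed.
split_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cosine similarity between two vectors.
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match estimated components to reference components
#'
#' One-to-one assignment of estimated component maps to reference maps by
#' absolute cosine similarity. The default greedy rule picks the best
#' remaining pair at each step (ties broken by component order); with
#' `method = "exhaustive"` all permutations are scored and the assignment
#' with maximal total |cosine| is returned (feasible for small numbers of
#' components, used for recovery checks).
#'
#' @param estimated matrix, regions x components (estimated loadings).
#' @param reference matrix, regions x components (reference loadings).
#' @param method "greedy" or "exhaustive".
#' @return list with `assignment` (for each reference column, the matched
#'   estimated column), `signs` (sign aligning each matched estimated column
#'   to its reference), and `similarity` (|cosine| per match).
#' @export
match_components <- function(estimated, reference, method = c("greedy", "exhaustive")) {
  method <- match.arg(method)
  kr <- ncol(reference); ke <- ncol(estimated)
  stopifnot(nrow(estimated) == nrow(reference), ke >= kr)
  S <- matrix(0, kr, ke)
  for (i in seq_len(kr)) for (j in seq_len(ke))
    S[i, j] <- cosine_sim(reference[, i], estimated[, j])
  A <- abs(S)
  assignment <- integer(kr)
  if (method == "greedy") {
    used <- logical(ke)
    remaining <- seq_len(kr)
    while (length(remaining)) {
      A2 <- A; A2[, used] <- -Inf; A2[setdiff(seq_len(kr), remaining), ] <- -Inf
      idx <- which(A2 == max(A2), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      assignment[idx[1]] <- idx[2]
      used[idx[2]] <- TRUE
      remaining <- setdiff(remaining, idx[1])
    }
  } else {
    cand <- seq_len(ke)
    if (ke > kr + 3) {
      # keep only plausible candidates so the permutation search stays small
      best <- apply(A, 2, max)
      cand <- sort(order(best, decreasing = TRUE)[seq_len(kr + 3)])
    }
    perms <- permutations_of(cand, kr)
    best <- -Inf
    for (p in perms) {
      tot <- sum(A[cbind(seq_len(kr), p)])
      if (tot > best) { best <- tot; assignment <- p }
    }
  }
  sims <- A[cbind(seq_len(kr), assignment)]
  signs <- sign(S[cbind(seq_len(kr), assignment)])
  signs[signs == 0] <- 1
  list(assignment = assignment, signs = signs, similarity = sims)
}

# All ordered selections of length k from x (k! * choose(n,k) lists).
permutations_of <- function(x, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i], k - 1)
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

stop_ctx <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
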