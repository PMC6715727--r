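#' Hypergeometric test of pairwise innervation independence
#'
#' Under independence, the number of axons innervating both regions
#' follows the hypergeometric distribution with parameters `N` (axons),
#' `n_a`, `n_b`. The two-tailed p-value is twice the smaller tail of the
#' observed overlap (capped at 1); independence is rejected at p < 0.05.
#' The observed conditional increase is
#' `(overlap / n_b) / (n_a / N)`.
#'
#' @param mat binary innervation matrix (axons x regions).
#' @param a,b region column names or indices.
#' @return list with `p_value`, `increase`, `reject`, `overlap`,
#'   `n_a`, `n_b`, `N`, and `flagged` (TRUE when a region is never
#'   innervated and the increase is undefined).
#' @export
test_pairwise_independence <- function(mat, a, b) {
  N <- nrow(mat)
  if (N < 1) stop("empty innervation matrix")
  va <- mat[, a] > 0
  vb <- mat[, b] > 0
  n_a <- sum(va); n_b <- sum(vb)
  k <- sum(va & vb)
  if (n_a == 0 || n_b == 0) {
    return(list(p_value = 1, increase = NA_real_, reject = FALSE,
                overlap = k, n_a = n_a, n_b = n_b, N = N, flagged = TRUE))
  }
  lower <- stats::phyper(k, n_a, N - n_a, n_b)
  upper <- stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  increase <- (k / n_b) / (n_a / N)
  list(p_value = p, increase = increase, reject = p < 0.05,
       overlap = k, n_a = n_a, n_b = n_b, N = N, flagged = FALSE)
}

#' Pairwise Hamming-distance distributions of innervation profiles
#'
#' Computes all pairwise Hamming distances within each of two profile
#' sets and compares the two distance distributions with a two-sample
#' Kolmogorov-Smirnov test. Used to compare reconstructed-axon data, the
#' tree model, and the naive first-order model.
#'
#' @param profiles_a,profiles_b binary matrices (profiles x regions) over
#'   the same region set.
#' @return list with `dist_a`, `dist_b` (numeric distance vectors),
#'   `ks_statistic` and `p_value`.
#' @export
compare_hamming_distributions <- function(profiles_a, profiles_b) {
  if (nrow(profiles_a) < 2 || nrow(profiles_b) < 2) {
    stop("need at least 2 profiles per set")
  }
  if (ncol(profiles_a) != ncol(profiles_b)) {
    stop("profile sets must cover the same region set")
  }
  da <- as.numeric(stats::dist(profiles_a, method = "manhattan"))
  db <- as.numeric(stats::dist(profiles_b, method = "manhattan"))
  ks <- suppressWarnings(stats::ks.test(da, db))
  list(dist_a = da, dist_b = db,
       ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Sample profiles from the naive first-order model
#'
#' The control model without interactions: each region is innervated
#' independently with its first-order probability.
#'
#' @param p named vector of first-order innervation probabilities per
#'   region (source region's own entry should be 0).
#' @param n number of profiles.
#' @param seed integer seed.
#' @return binary matrix `n x length(p)`.
#' @export
sample_naive_profiles <- function(p, n, seed = 0) {
  local_seed(seed, {
    out <- matrix(stats::runif(n * length(p)) <
                    matrix(p, n, length(p), byrow = TRUE), n, length(p)) * 1L
    colnames(out) <- names(p)
    out
  })
}
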