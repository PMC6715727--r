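#' Predicted single-axon innervation probability
#'
#' Innervation probability is proportional to the square root of the
#' normalized projection strength (axon amount in the target over source
#' volume), with a class-specific constant: 0.5 for L2/3 and L6, 0.33 for
#' L4 and L5PT, 0.22 for L5IT. Clipped at 1.
#'
#' @param nps normalized projection strength (>= 0, vectorized).
#' @param class projection class, one of `"L2/3"`, `"L4"`, `"L5IT"`,
#'   `"L5PT"`, `"L6"`.
#' @return probability in `[0, 1]`.
#' @export
innervation_probability <- function(nps, class) {
  k <- c("L2/3" = 0.5, "L6" = 0.5, "L4" = 0.33, "L5PT" = 0.33,
         "L5IT" = 0.22)
  if (!class %in% names(k)) stop("unknown projection class: ", class)
  if (any(nps < 0)) stop("normalized projection strength must be >= 0")
  pmin(1, k[[class]] * sqrt(nps))
}

#' Tree topology from a community-detection resolution sweep
#'
#' Builds the skeleton of the projection-type tree from a matrix of
#' normalized connection densities. Starting at resolution
#' `gamma = gamma_from` (high enough that every region is its own
#' community, each a leaf), the resolution is lowered stepwise to 0; a
#' pair of current communities merges into a new inner node whenever a
#' detected community contains more than half of the regions of each.
#' Simultaneous multi-way merges are processed as successive binary merges
#' in lexicographic region order, so the tree is binary; the root is
#' placed when resolution reaches 0. Community detection is the seeded
#' Louvain heuristic on the symmetrized matrix `(A + t(A)) / 2`.
#'
#' @param ncd square non-negative matrix of normalized connection
#'   densities with region dimnames.
#' @param gamma_from,gamma_to,gamma_step resolution sweep (6, 0, 0.05).
#' @param seed integer seed (one sub-stream per resolution step).
#' @return a `ptype_tree` skeleton (no edge probabilities).
#' @export
build_tree_topology <- function(ncd, gamma_from = 6, gamma_to = 0,
                                gamma_step = 0.05, seed = 0) {
  ncd <- as.matrix(ncd)
  if (length(ncd) == 0) stop("empty connection-density matrix")
  if (is.null(rownames(ncd))) {
    dimnames(ncd) <- list(as.character(seq_len(nrow(ncd))),
                          as.character(seq_len(nrow(ncd))))
  }
  regions <- rownames(ncd)
  A <- (ncd + t(ncd)) / 2
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)

  n <- length(regions)
  parent <- rep(NA_integer_, n)
  leaf_label <- regions
  # active communities: node id -> region index set
  active <- stats::setNames(lapply(seq_len(n), identity),
                            as.character(seq_len(n)))
  first_region <- function(ids) min(regions[ids])

  merge_pair <- function(a, b) {
    new_id <- length(parent) + 1L
    parent[a] <<- new_id
    parent[b] <<- new_id
    parent <<- c(parent, NA_integer_)
    leaf_label <<- c(leaf_label, NA_character_)
    active[[as.character(new_id)]] <<- c(active[[as.character(a)]],
                                         active[[as.character(b)]])
    active[[as.character(a)]] <<- NULL
    active[[as.character(b)]] <<- NULL
    new_id
  }

  gammas <- seq(gamma_from, gamma_to, by = -abs(gamma_step))
  if (gammas[length(gammas)] > gamma_to) gammas <- c(gammas, gamma_to)
  for (gamma in gammas) {
    if (length(active) <= 1) break
    memb <- local_seed(derive_seed(seed, sprintf("louvain-%.4f", gamma)), {
      if (gamma <= 0 || sum(A) == 0) rep(1L, n) else
        igraph::membership(igraph::cluster_louvain(g, resolution = gamma))
    })
    for (comm in unique(memb)) {
      inside <- which(memb == comm)
      repeat {
        ids <- names(active)
        frac <- vapply(ids, function(i) {
          mean(active[[i]] %in% inside)
        }, numeric(1))
        cand <- ids[frac > 0.5]
        if (length(cand) < 2) break
        # lexicographic region order
        ord <- order(vapply(cand, function(i) first_region(active[[i]]),
                            character(1)))
        merge_pair(as.integer(cand[ord[1]]), as.integer(cand[ord[2]]))
      }
    }
  }
  # root at gamma = 0: merge any remaining communities binarily
  while (length(active) > 1) {
    ids <- names(active)
    ord <- order(vapply(ids, function(i) first_region(active[[i]]),
                        character(1)))
    merge_pair(as.integer(ids[ord[1]]), as.integer(ids[ord[2]]))
  }
  ptype_tree(parent, leaf_label)
}

#' Fit directed edge probabilities on a tree skeleton
#'
#' Recursive leaf-to-root pass over sibling motifs. For siblings `T1`,
#' `T2` with parent `R`, the four directed edge lengths solve (in least
#' squares) the linear system: the up-length difference equals the mean
#' row difference of the working distance matrix over reference nodes
#' outside both subtrees; the down-length difference equals the mean
#' column difference; and the two cross-sibling distances equal the sums
#' through the parent. The system is structurally rank-deficient (its
#' solutions form a one-parameter family), so the minimum-norm
#' least-squares solution is taken and shifted along the family to the
#' nearest all-non-negative point when one exists; remaining negative
#' lengths are clamped to 0 and probabilities to `[epsilon, 1]`, and the
#' motif is flagged. After each motif the parent inherits the averaged
#' distances of its children for the next level.
#'
#' @param skeleton a `ptype_tree` skeleton (binary, from
#'   [build_tree_topology()]).
#' @param M leaf x leaf matrix of `-log10` predicted innervation
#'   probabilities (dimnames = leaf labels). Non-finite entries (absent
#'   projections) are replaced by `-log10(epsilon)`.
#' @param epsilon probability floor (default 1e-6).
#' @return a fitted `ptype_tree`; attribute `flagged` lists motifs where
#'   clamping was required.
#' @export
fit_edge_probabilities <- function(skeleton, M, epsilon = 1e-6) {
  lv <- skeleton$leaves
  M <- as.matrix(M)[lv, lv, drop = FALSE]
  lmax <- -log10(epsilon)
  M[!is.finite(M)] <- lmax
  diag(M) <- 0

  nodes <- skeleton$nodes
  nn <- nrow(nodes)
  up_len <- rep(NA_real_, nn)
  down_len <- rep(NA_real_, nn)
  # working distance matrix over active nodes, keyed by node id
  act <- as.character(nodes$id[nodes$is_leaf])
  D <- matrix(0, length(act), length(act), dimnames = list(act, act))
  idx <- match(nodes$label[nodes$is_leaf], lv)
  D[, ] <- M[idx, idx]
  flagged <- character()

  inner <- nodes$id[!nodes$is_leaf]
  inner <- inner[order(inner)]  # creation order = post-order (children first)
  for (R in inner) {
    ch <- nodes$id[!is.na(nodes$parent) & nodes$parent == R]
    if (length(ch) != 2) stop("fitting requires a binary skeleton")
    t1 <- as.character(ch[1]); t2 <- as.character(ch[2])
    O <- setdiff(rownames(D), c(t1, t2))
    if (length(O) > 0) {
      d_row <- mean(D[t1, O] - D[t2, O])
      d_col <- mean(D[O, t1] - D[O, t2])
      A <- rbind(c(1, -1, 0, 0),
                 c(0, 0, 1, -1),
                 c(1, 0, 0, 1),
                 c(0, 1, 1, 0))
      b <- c(d_row, d_col, D[t1, t2], D[t2, t1])
    } else {
      A <- rbind(c(1, 0, 0, 1),
                 c(0, 1, 1, 0))
      b <- c(D[t1, t2], D[t2, t1])
    }
    w <- as.numeric(MASS::ginv(A) %*% b)  # min-norm least squares
    up_len[ch[1]] <- w[1]; up_len[ch[2]] <- w[2]
    down_len[ch[1]] <- w[3]; down_len[ch[2]] <- w[4]
    if (length(O) > 0) {
      r <- as.character(R)
      newD <- matrix(0, length(O) + 1, length(O) + 1,
                     dimnames = list(c(O, r), c(O, r)))
      newD[O, O] <- D[O, O, drop = FALSE]
      newD[r, O] <- (D[t1, O] - w[1] + D[t2, O] - w[2]) / 2
      newD[O, r] <- (D[O, t1] - w[3] + D[O, t2] - w[4]) / 2
      D <- newD
    } else {
      D <- matrix(0, 1, 1, dimnames = list(as.character(R), as.character(R)))
    }
  }
  # Each motif's least-squares residual is invariant along a one-parameter
  # gauge (shifting both child up-lengths up and both down-lengths down,
  # compensated on the parent's own edge leaves every leaf-to-leaf path
  # length unchanged). The min-norm solution can therefore carry negative
  # lengths even on perfectly additive inputs; repair the gauge globally
  # so all lengths land in [0, -log10(epsilon)] whenever that is feasible.
  rep_ <- gauge_repair(nodes, up_len, down_len, lmax)
  up_len <- rep_$up; down_len <- rep_$down
  flagged <- c(flagged, rep_$flagged)
  bad <- which(up_len < -1e-9 | down_len < -1e-9 |
                 up_len > lmax + 1e-9 | down_len > lmax + 1e-9)
  if (length(bad)) flagged <- c(flagged, paste0("edge", bad))
  up_len <- pmin(pmax(up_len, 0), lmax)
  down_len <- pmin(pmax(down_len, 0), lmax)
  out <- ptype_tree(nodes$parent, nodes$label,
                    up_p = 10^(-up_len), down_p = 10^(-down_len),
                    epsilon = epsilon)
  attr(out, "flagged") <- unique(flagged)
  out
}

# Resolve the per-motif gauge freedom: one shift delta per internal node,
# where the up/down lengths of node X's parent edge become
# up + delta_P - delta_X and down - delta_P + delta_X (delta = 0 for
# leaves). Feasibility is a difference-constraint system on the tree,
# solved exactly by an interval DP (bottom-up intervals, top-down choice).
gauge_repair <- function(nodes, up_len, down_len, lmax) {
  n <- nrow(nodes)
  is_leaf <- nodes$is_leaf
  kids <- split(nodes$id[!is.na(nodes$parent)],
                nodes$parent[!is.na(nodes$parent)])
  # per-edge allowed range for (delta_X - delta_P):
  # up' = up + dP - dX in [0, lmax]; down' = down - dP + dX in [0, lmax]
  A <- pmax(-down_len, up_len - lmax)
  B <- pmin(up_len, lmax - down_len)
  flagged <- character()
  lo <- rep(-Inf, n); hi <- rep(Inf, n)
  inner <- sort(nodes$id[!is_leaf])
  for (X in inner) {             # creation order: children before parents
    for (c_ in kids[[as.character(X)]]) {
      if (is_leaf[c_]) {
        lo[X] <- max(lo[X], -B[c_])
        hi[X] <- min(hi[X], -A[c_])
      } else {
        lo[X] <- max(lo[X], lo[c_] - B[c_])
        hi[X] <- min(hi[X], hi[c_] - A[c_])
      }
    }
    if (lo[X] > hi[X]) {         # inconsistent input: no exact gauge
      flagged <- c(flagged, paste0("gauge", X))
      mid <- (lo[X] + hi[X]) / 2
      lo[X] <- hi[X] <- mid
    }
  }
  delta <- numeric(n)
  root <- nodes$id[is.na(nodes$parent)]
  delta[root] <- min(max(0, lo[root]), hi[root])
  for (X in rev(inner)) {        # top-down: parents before children
    for (c_ in kids[[as.character(X)]]) {
      if (is_leaf[c_]) next
      l <- max(lo[c_], delta[X] + A[c_])
      h <- min(hi[c_], delta[X] + B[c_])
      if (l > h) { flagged <- c(flagged, paste0("gauge", c_)); h <- l }
      delta[c_] <- (l + h) / 2
    }
  }
  P <- nodes$parent
  adj_up <- up_len
  adj_dn <- down_len
  has_p <- !is.na(P)
  adj_up[has_p] <- up_len[has_p] + delta[P[has_p]] - delta[nodes$id[has_p]]
  adj_dn[has_p] <- down_len[has_p] - delta[P[has_p]] + delta[nodes$id[has_p]]
  list(up = adj_up, down = adj_dn, flagged = flagged)
}

#' Fit a projection-type tree to an innervation-probability matrix
#'
#' Convenience wrapper: builds the topology from the normalized connection
#' densities and fits the directed edge probabilities to the `-log10`
#' first-order innervation probabilities.
#'
#' @param ncd region x region normalized connection densities.
#' @param P region x region first-order innervation probabilities.
#' @param gamma_step,seed,epsilon see [build_tree_topology()] and
#'   [fit_edge_probabilities()].
#' @return a fitted `ptype_tree`.
#' @export
fit_ptype_tree <- function(ncd, P, gamma_step = 0.05, seed = 0,
                           epsilon = 1e-6) {
  skeleton <- build_tree_topology(ncd, gamma_step = gamma_step, seed = seed)
  fit_edge_probabilities(skeleton, -log10(P), epsilon = epsilon)
}
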