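# Shared fixture builders and independent oracles. The oracles enumerate or
# brute-force the quantities the package computes analytically; they never
# call the code paths they check.

mini_atlas <- function(...) build_synthetic_atlas(...)

# random binary tree over nl leaves with directed probabilities in [lo, hi]
random_ptype_tree <- function(nl, seed, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  parent <- rep(NA_integer_, nl)
  labs <- paste0("R", sprintf("%02d", seq_len(nl)))
  act <- seq_len(nl)
  while (length(act) > 1) {
    pick <- sample(length(act), 2)
    new <- length(parent) + 1L
    parent[act[pick]] <- new
    parent <- c(parent, NA_integer_)
    labs <- c(labs, NA)
    act <- c(act[-pick], new)
  }
  n <- length(parent)
  up <- stats::runif(n, lo, hi)
  dn <- stats::runif(n, lo, hi)
  up[is.na(parent)] <- NA
  dn[is.na(parent)] <- NA
  ptype_tree(parent, labs, up, dn)
}

# directed edges reachable from `source`, in BFS order: data.frame(from, to, p)
tree_directed_edges <- function(tree, source) {
  src <- unname(tree$leaf_ids[source])
  nn <- nrow(tree$nodes)
  kids <- split(tree$nodes$id[!is.na(tree$nodes$parent)],
                tree$nodes$parent[!is.na(tree$nodes$parent)])
  visited <- logical(nn)
  visited[src] <- TRUE
  queue <- src
  from <- integer(); to <- integer(); p <- numeric()
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    nb <- c(tree$nodes$parent[u], kids[[as.character(u)]])
    nb <- nb[!is.na(nb)]
    for (v in nb) {
      if (visited[v]) next
      visited[v] <- TRUE
      pe <- if (!is.na(tree$nodes$parent[u]) && tree$nodes$parent[u] == v) {
        tree$nodes$up_p[u]
      } else {
        tree$nodes$down_p[v]
      }
      from <- c(from, u); to <- c(to, v); p <- c(p, pe)
      queue <- c(queue, v)
    }
  }
  data.frame(from = from, to = to, p = p)
}

# exhaustive enumeration of percolation outcomes: exact marginal and joint
# innervation probabilities for axons from `source`
enumerate_innervation <- function(tree, source) {
  ed <- tree_directed_edges(tree, source)
  E <- nrow(ed)
  stopifnot(E <= 16)
  src <- unname(tree$leaf_ids[source])
  nn <- nrow(tree$nodes)
  lv <- tree$leaves
  marg <- stats::setNames(numeric(length(lv)), lv)
  joint <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (mask in 0:(2^E - 1)) {
    cross <- bitwAnd(mask, 2^(seq_len(E) - 1)) > 0
    prob <- prod(ifelse(cross, ed$p, 1 - ed$p))
    reach <- logical(nn)
    reach[src] <- TRUE
    for (e in seq_len(E)) {
      reach[ed$to[e]] <- reach[ed$from[e]] && cross[e]
    }
    r <- lv[reach[tree$leaf_ids]]
    r <- setdiff(r, source)
    marg[r] <- marg[r] + prob
    joint[r, r] <- joint[r, r] + prob
  }
  list(marg = marg, joint = joint)
}

# small class-split fixture over a 2-region-per-hemisphere atlas
tiny_split <- function(atlas, seed = 1) {
  R <- atlas$n_regions_per_hemisphere
  base <- as.character(seq_len(R))
  set.seed(seed)
  ipsi <- matrix(stats::runif(R * R, 0.1, 1), R, R,
                 dimnames = list(base, base))
  diag(ipsi) <- 0
  wt <- projection_matrix(ipsi, ipsi / 2)
  V <- atlas$region_volumes[base]
  sc <- compute_scaling_factor(wt, V, long_range_budget = 1e6)
  mods <- atlas$modules[base]
  nm <- length(unique(mods))
  w <- lapply(1:2, function(i) {
    matrix(stats::runif(nm * nm, 0.2, 1), nm, nm,
           dimnames = list(as.character(sort(unique(mods))),
                           as.character(sort(unique(mods)))))
  })
  names(w) <- c("L2/3", "L5IT")
  split_by_class(sc$scaled, w, mods)
}
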