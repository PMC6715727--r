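#' Neuron-to-neuron connectome instance
#'
#' Light container for micro-structure analyses: a directed edge list over
#' neuron ids plus the neuron table (regions and flat positions). Multiple
#' synapses between a pair count as one connection.
#'
#' @param edges data.frame with `source_neuron`, `target_neuron`.
#' @param neurons neuron table with `id`, `region`, `flat_x`, `flat_y`.
#' @return object of class `connectome` holding a sparse adjacency matrix.
#' @export
connectome <- function(edges, neurons) {
  n <- max(neurons$id)
  adj <- Matrix::sparseMatrix(i = edges$source_neuron,
                              j = edges$target_neuron,
                              x = 1, dims = c(n, n), use.last.ij = TRUE)
  adj@x[] <- 1
  structure(list(adj = adj, neurons = neurons), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("Connectome:", nrow(x$neurons), "neurons,",
      length(x$adj@x), "connections\n")
  invisible(x)
}

#' Reciprocal-connectivity overexpression under the mapping
#'
#' Samples paired subvolumes: a disc of `radius` around a random neuron of
#' region B, its center mapped into region A through the topographic
#' mapping and shifted by `offset` in a seeded random direction, and a
#' disc of the same radius there. Within each sampled pair the
#' unidirectional connection probabilities and the reciprocal-pair
#' probability are counted; the expected reciprocal probability under
#' independence is the product of the unidirectional ones, and the
#' overexpression ratio is observed over expected (pooled over samples).
#'
#' @param conn a `connectome`.
#' @param region_a,region_b region ids.
#' @param mapping_ba `topo_mapping` from region B's flat space into
#'   region A's.
#' @param radius sampling radius in micrometers (> 0).
#' @param offset sampling offset in micrometers (>= 0).
#' @param n_samples number of sampled subvolume pairs.
#' @param seed integer seed.
#' @return list with `p_uni_ab`, `p_uni_ba`, `p_recip_observed`,
#'   `p_recip_expected`, `ratio`, `n_used`.
#' @export
reciprocal_overexpression <- function(conn, region_a, region_b, mapping_ba,
                                      radius, offset = 0, n_samples = 20,
                                      seed = 0) {
  stopifnot(radius > 0, offset >= 0)
  nb <- conn$neurons[conn$neurons$region == region_b, , drop = FALSE]
  na_ <- conn$neurons[conn$neurons$region == region_a, , drop = FALSE]
  if (nrow(nb) < 2 || nrow(na_) < 2) stop("a region has fewer than 2 neurons")
  adj <- conn$adj
  local_seed(seed, {
    tot_ab <- 0; tot_ba <- 0; tot_rec <- 0; tot_pairs <- 0
    sum_exp <- 0; n_used <- 0
    for (s in seq_len(n_samples)) {
      cb <- nb[sample.int(nrow(nb), 1), ]
      in_b <- which((nb$flat_x - cb$flat_x)^2 +
                      (nb$flat_y - cb$flat_y)^2 <= radius^2)
      ca <- map_source_to_target(cbind(cb$flat_x, cb$flat_y), mapping_ba)$point
      if (offset > 0) {
        ang <- stats::runif(1, 0, 2 * pi)
        ca <- ca + offset * c(cos(ang), sin(ang))
      }
      in_a <- which((na_$flat_x - ca[1])^2 + (na_$flat_y - ca[2])^2 <=
                      radius^2)
      if (length(in_a) < 2 || length(in_b) < 2) next
      A <- na_$id[in_a]; B <- nb$id[in_b]
      ab <- as.matrix(adj[A, B, drop = FALSE])
      ba <- t(as.matrix(adj[B, A, drop = FALSE]))
      npairs <- length(A) * length(B)
      e_ab <- sum(ab); e_ba <- sum(ba); e_rec <- sum(ab * ba)
      tot_ab <- tot_ab + e_ab; tot_ba <- tot_ba + e_ba
      tot_rec <- tot_rec + e_rec; tot_pairs <- tot_pairs + npairs
      sum_exp <- sum_exp + (e_ab / npairs) * (e_ba / npairs) * npairs
      n_used <- n_used + 1
    }
    if (n_used == 0) stop("all sampled subvolumes were empty")
    p_ab <- tot_ab / tot_pairs
    p_ba <- tot_ba / tot_pairs
    p_rec <- tot_rec / tot_pairs
    p_exp <- sum_exp / tot_pairs
    list(p_uni_ab = p_ab, p_uni_ba = p_ba, p_recip_observed = p_rec,
         p_recip_expected = p_exp,
         ratio = if (p_exp > 0) p_rec / p_exp else NA_real_,
         n_used = n_used)
  })
}

#' Cross-region triplet motif counts
#'
#' Samples one neuron from each of three regions per triplet and counts
#' the 64 directed connectivity states over the six ordered region pairs.
#' The expectation under independence uses the six empirical pairwise
#' edge probabilities between the full region populations; per-motif
#' z-scores are `(observed - n p) / sqrt(n p (1 - p))`.
#'
#' @param conn a `connectome`.
#' @param regions vector of three region ids.
#' @param n_samples number of triplets.
#' @param seed integer seed.
#' @return data.frame with 64 rows: `motif` (bit string over edges
#'   AB, BA, AC, CA, BC, CB), `count`, `expected`, `z`.
#' @export
triplet_motif_counts <- function(conn, regions, n_samples = 10000,
                                 seed = 0) {
  stopifnot(length(regions) == 3)
  pops <- lapply(regions, function(r) {
    ids <- conn$neurons$id[conn$neurons$region == r]
    if (length(ids) < 1) stop("region ", r, " has no neurons")
    ids
  })
  adj <- conn$adj
  # pairwise edge probabilities over the full populations
  pair_idx <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  p_pair <- apply(pair_idx, 1, function(ij) {
    sum(adj[pops[[ij[1]]], pops[[ij[2]]], drop = FALSE]) /
      (length(pops[[ij[1]]]) * length(pops[[ij[2]]]))
  })
  local_seed(seed, {
    a <- pops[[1]][sample.int(length(pops[[1]]), n_samples, replace = TRUE)]
    b <- pops[[2]][sample.int(length(pops[[2]]), n_samples, replace = TRUE)]
    c_ <- pops[[3]][sample.int(length(pops[[3]]), n_samples, replace = TRUE)]
    bits <- cbind(adj[cbind(a, b)], adj[cbind(b, a)],
                  adj[cbind(a, c_)], adj[cbind(c_, a)],
                  adj[cbind(b, c_)], adj[cbind(c_, b)]) > 0
    state <- as.integer(bits %*% 2^(0:5))
    count <- tabulate(state + 1L, nbins = 64L)
    motif_bits <- t(vapply(0:63, function(s) as.integer(intToBits(s)[1:6]),
                           integer(6)))
    p_motif <- apply(motif_bits, 1, function(m) {
      prod(ifelse(m == 1, p_pair, 1 - p_pair))
    })
    expected <- n_samples * p_motif
    z <- (count - expected) / sqrt(pmax(n_samples * p_motif * (1 - p_motif),
                                        .Machine$double.eps))
    data.frame(
      motif = apply(motif_bits, 1, paste, collapse = ""),
      count = count, expected = expected, z = z)
  })
}

#' Degree-preserving control of a bipartite inter-region graph
#'
#' Edge-swap randomization: repeatedly swaps the targets of two random
#' edges, which preserves every neuron's in- and out-degree exactly. The
#' number of attempted swaps is `swap_factor` times the edge count
#' (burn-in at least 10x edges by default).
#'
#' @param el 2-column matrix of directed edges (source id, target id).
#' @param swap_factor attempted swaps per edge (default 10).
#' @param seed integer seed.
#' @return the shuffled edge matrix.
#' @export
degree_preserving_shuffle <- function(el, swap_factor = 10, seed = 0) {
  m <- nrow(el)
  if (m < 2) return(el)
  local_seed(seed, {
    key <- function(e) paste(e[, 1], e[, 2])
    existing <- new.env(hash = TRUE)
    for (k in key(el)) assign(k, TRUE, envir = existing)
    n_swaps <- ceiling(swap_factor * m)
    pick1 <- sample.int(m, n_swaps, replace = TRUE)
    pick2 <- sample.int(m, n_swaps, replace = TRUE)
    for (s in seq_len(n_swaps)) {
      i <- pick1[s]; j <- pick2[s]
      if (i == j) next
      a1 <- el[i, 1]; b1 <- el[i, 2]
      a2 <- el[j, 1]; b2 <- el[j, 2]
      if (b1 == b2 || a1 == a2) next
      k1 <- paste(a1, b2); k2 <- paste(a2, b1)
      if (exists(k1, envir = existing, inherits = FALSE) ||
          exists(k2, envir = existing, inherits = FALSE)) next
      rm(list = c(paste(a1, b1), paste(a2, b2)), envir = existing)
      assign(k1, TRUE, envir = existing)
      assign(k2, TRUE, envir = existing)
      el[i, 2] <- b2; el[j, 2] <- b1
    }
    el
  })
}

#' Module-to-module edge-density analysis with a degree-preserving control
#'
#' Detects within-region modules by seeded community detection (Louvain,
#' on the symmetrized intra-region graph) in each of two regions, then
#' computes the edge density (connections over possible pairs) between
#' every pair of (source module in A, target module in B). The width of
#' the edge-density distribution at half its modal height (from a kernel
#' density estimate with the default bandwidth rule) is compared against
#' degree-preserving edge-swap controls of the inter-region graph.
#'
#' @param conn a `connectome`.
#' @param region_a,region_b region ids (source, target).
#' @param n_controls number of shuffled controls (default 10).
#' @param resolution Louvain resolution for within-region modules.
#' @param seed integer seed.
#' @return list with `density_matrix`, `modules_a`, `modules_b`,
#'   `width_model`, `width_controls`, and the per-control density
#'   matrices' widths.
#' @export
module_edge_density_analysis <- function(conn, region_a, region_b,
                                         n_controls = 10, resolution = 1,
                                         seed = 0) {
  ids_a <- conn$neurons$id[conn$neurons$region == region_a]
  ids_b <- conn$neurons$id[conn$neurons$region == region_b]
  mod_a <- detect_modules(conn$adj[ids_a, ids_a, drop = FALSE],
                          resolution, derive_seed(seed, "modA"))
  mod_b <- detect_modules(conn$adj[ids_b, ids_b, drop = FALSE],
                          resolution, derive_seed(seed, "modB"))
  if (length(unique(mod_a)) < 2 || length(unique(mod_b)) < 2) {
    stop("a region yielded fewer than 2 within-region modules")
  }
  bip <- conn$adj[ids_a, ids_b, drop = FALSE]
  dens <- module_density_matrix(bip, mod_a, mod_b)
  width_model <- width_at_half_height(as.numeric(dens))
  el <- which(as.matrix(bip) > 0, arr.ind = TRUE)
  width_controls <- vapply(seq_len(n_controls), function(cix) {
    sh <- degree_preserving_shuffle(el, seed = derive_seed(seed,
                                                           paste0("ctl", cix)))
    bip_c <- Matrix::sparseMatrix(i = sh[, 1], j = sh[, 2], x = 1,
                                  dims = dim(bip))
    width_at_half_height(as.numeric(module_density_matrix(bip_c, mod_a,
                                                          mod_b)))
  }, numeric(1))
  list(density_matrix = dens, modules_a = mod_a, modules_b = mod_b,
       width_model = width_model, width_controls = width_controls)
}

detect_modules <- function(adj, resolution, seed) {
  sym <- (adj + Matrix::t(adj)) / 2
  g <- igraph::graph_from_adjacency_matrix(sym, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  local_seed(seed, {
    as.integer(igraph::membership(
      igraph::cluster_louvain(g, resolution = resolution)))
  })
}

module_density_matrix <- function(bip, mod_a, mod_b) {
  ka <- sort(unique(mod_a)); kb <- sort(unique(mod_b))
  out <- matrix(0, length(ka), length(kb))
  for (ia in seq_along(ka)) {
    ra <- which(mod_a == ka[ia])
    for (ib in seq_along(kb)) {
      rb <- which(mod_b == kb[ib])
      out[ia, ib] <- sum(bip[ra, rb, drop = FALSE]) /
        (length(ra) * length(rb))
    }
  }
  out
}

#' Width at half height of a smoothed distribution
#'
#' Kernel density estimate (Gaussian kernel, default `nrd0` bandwidth);
#' the width is the distance between the outermost points where the
#' density reaches half its modal height.
#'
#' @param x numeric sample.
#' @return the width (same units as `x`).
#' @export
width_at_half_height <- function(x) {
  if (length(unique(x)) < 2) return(0)
  d <- stats::density(x)
  above <- which(d$y >= max(d$y) / 2)
  d$x[max(above)] - d$x[min(above)]
}
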