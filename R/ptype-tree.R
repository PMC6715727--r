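#' Projection-type generating tree
#'
#' A directed tree whose leaves are brain regions. Each undirected link
#' carries two directed crossing probabilities (child-to-parent `up_p`,
#' parent-to-child `down_p`); edge length is `-log10(p)`. An axon
#' originating at a source leaf percolates outward: every directed edge
#' reached is crossed independently with its probability, and once an edge
#' is not crossed it never is. Leaves reached are innervated — the axon's
#' projection type.
#'
#' @param parent integer vector: parent node id per node (`NA` for root).
#' @param leaf_label character vector: region name per node (`NA`/empty for
#'   inner nodes).
#' @param up_p,down_p crossing probabilities per node's link to its parent
#'   (`NA` for the root). Values are clamped to `[epsilon, 1]`.
#' @param epsilon probability floor (default 1e-6).
#' @return object of class `ptype_tree`.
#' @export
ptype_tree <- function(parent, leaf_label, up_p = NA_real_,
                       down_p = NA_real_, epsilon = 1e-6) {
  n <- length(parent)
  up_p <- rep(up_p, length.out = n)
  down_p <- rep(down_p, length.out = n)
  leaf_label <- as.character(leaf_label)
  is_leaf <- !is.na(leaf_label) & nzchar(leaf_label)
  if (sum(is.na(parent)) != 1) stop("tree must have exactly one root")
  clamp <- function(p) ifelse(is.na(p), NA_real_, pmin(1, pmax(epsilon, p)))
  nodes <- data.frame(id = seq_len(n), parent = parent,
                      label = ifelse(is_leaf, leaf_label, NA_character_),
                      is_leaf = is_leaf,
                      up_p = clamp(up_p), down_p = clamp(down_p),
                      stringsAsFactors = FALSE)
  # connectivity / acyclicity: every node must reach the root
  root <- which(is.na(parent))
  for (v in seq_len(n)) {
    seen <- logical(n); u <- v
    while (!is.na(u)) {
      if (seen[u]) stop("cycle in tree structure")
      seen[u] <- TRUE
      u <- parent[u]
    }
  }
  leaves <- nodes$label[nodes$is_leaf]
  if (anyDuplicated(leaves)) stop("duplicate leaf labels")
  structure(list(nodes = nodes, root = root, leaves = leaves,
                 leaf_ids = stats::setNames(nodes$id[nodes$is_leaf], leaves),
                 epsilon = epsilon),
            class = "ptype_tree")
}

#' @export
print.ptype_tree <- function(x, ...) {
  cat("Projection-type tree:", length(x$leaves), "leaves,",
      nrow(x$nodes) - length(x$leaves), "inner nodes\n")
  if (!all(is.na(x$nodes$up_p[-x$root]))) {
    cat("  edge probabilities in [",
        signif(min(x$nodes$up_p, x$nodes$down_p, na.rm = TRUE), 3), ", ",
        signif(max(x$nodes$up_p, x$nodes$down_p, na.rm = TRUE), 3), "]\n",
        sep = "")
  } else {
    cat("  skeleton only (edge probabilities not yet fitted)\n")
  }
  invisible(x)
}

node_ancestors <- function(tree, id) {
  out <- integer()
  while (!is.na(id)) {
    out <- c(out, id)
    id <- tree$nodes$parent[id]
  }
  out
}

# node sequence of the unique path between two node ids (inclusive)
node_path <- function(tree, a, b) {
  aa <- node_ancestors(tree, a)
  bb <- node_ancestors(tree, b)
  common <- intersect(aa, bb)
  lca <- common[1]  # ancestors listed bottom-up; first common is the lca
  c(aa[seq_len(match(lca, aa))], rev(bb[seq_len(match(lca, bb) - 1)]))
}

# directed path length (-log10 probability) along the node sequence
path_length_nodes <- function(tree, path) {
  if (length(path) < 2) return(0)
  len <- 0
  for (i in seq_len(length(path) - 1)) {
    u <- path[i]; v <- path[i + 1]
    p <- if (!is.na(tree$nodes$parent[u]) && tree$nodes$parent[u] == v) {
      tree$nodes$up_p[u]      # stepping up out of u
    } else {
      tree$nodes$down_p[v]    # stepping down into v
    }
    if (is.na(p)) stop("edge probability not fitted")
    len <- len - log10(p)
  }
  len
}

leaf_id <- function(tree, leaf) {
  id <- tree$leaf_ids[as.character(leaf)]
  if (is.na(id)) stop("unknown region: ", leaf)
  unname(id)
}

#' First-order innervation probability along the tree
#'
#' `P(S -> T) = 10^(-L(S, T))` where `L` is the directed path length (sum
#' of `-log10` crossing probabilities) from the source leaf to the target
#' leaf.
#'
#' @param tree a fitted `ptype_tree`.
#' @param S,T distinct leaf labels.
#' @return probability in `(0, 1]`.
#' @export
path_probability <- function(tree, S, T) {
  if (identical(as.character(S), as.character(T))) {
    stop("within-region innervation is local connectivity, not modeled")
  }
  p <- node_path(tree, leaf_id(tree, S), leaf_id(tree, T))
  10^(-path_length_nodes(tree, p))
}

#' Matrix of pairwise path lengths between leaves
#' @param tree a fitted `ptype_tree`.
#' @return leaf x leaf matrix of directed path lengths (`-log10` scale;
#'   diagonal 0).
#' @export
predicted_length_matrix <- function(tree) {
  lv <- tree$leaves
  n <- length(lv)
  L <- matrix(0, n, n, dimnames = list(lv, lv))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a != b) {
      L[a, b] <- path_length_nodes(
        tree, node_path(tree, leaf_id(tree, lv[a]), leaf_id(tree, lv[b])))
    }
  }
  L
}

#' Conditional innervation increase
#'
#' The factor by which knowing that an axon from `S` innervates `T2`
#' raises the probability that it also innervates `T1`:
#' `I = P(T1 | T2) / P(T1) = 10^{L(S -> J)}`, where `J` is the lowest
#' common ancestor of `T1` and `T2` in the tree rooted at the source leaf
#' `S` (the node where the paths from `S` to the two targets diverge).
#' Always >= 1: shared path segments only ever increase co-innervation.
#'
#' @param tree a fitted `ptype_tree`.
#' @param S,T1,T2 distinct leaf labels.
#' @return conditional increase (>= 1). Symmetric in `T1`, `T2`.
#' @export
conditional_increase <- function(tree, S, T1, T2) {
  labs <- as.character(c(S, T1, T2))
  if (anyDuplicated(labs)) stop("S, T1, T2 must be distinct leaves")
  s <- leaf_id(tree, S)
  p1 <- node_path(tree, s, leaf_id(tree, T1))
  p2 <- node_path(tree, s, leaf_id(tree, T2))
  # divergence node: last node common to both paths walking from S
  k <- 1
  while (k < min(length(p1), length(p2)) && p1[k + 1] == p2[k + 1]) k <- k + 1
  10^path_length_nodes(tree, p1[seq_len(k)])
}

#' Sample innervation profiles from the tree model
#'
#' Percolation from the source leaf: edges are visited outward in
#' breadth-first order; each directed edge reached is crossed with its
#' probability, independently per axon. The source leaf's own column is 0
#' (an axon trivially occupies its own region).
#'
#' @param tree a fitted `ptype_tree`.
#' @param source source leaf label.
#' @param n number of axons (>= 1).
#' @param seed integer seed.
#' @return binary matrix `n x n_leaves` with leaf labels as columns.
#' @export
sample_innervation_profiles <- function(tree, source, n, seed = 0) {
  stopifnot(n >= 1)
  src <- leaf_id(tree, source)
  nn <- nrow(tree$nodes)
  # undirected adjacency via parent pointers
  kids <- split(tree$nodes$id[!is.na(tree$nodes$parent)],
                tree$nodes$parent[!is.na(tree$nodes$parent)])
  local_seed(seed, {
    reached <- matrix(FALSE, n, nn)
    reached[, src] <- TRUE
    # BFS from source over the undirected skeleton
    visited <- logical(nn); visited[src] <- TRUE
    queue <- src
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- c(tree$nodes$parent[u], kids[[as.character(u)]])
      nb <- nb[!is.na(nb)]
      for (v in nb) {
        if (visited[v]) next
        visited[v] <- TRUE
        p <- if (!is.na(tree$nodes$parent[u]) && tree$nodes$parent[u] == v) {
          tree$nodes$up_p[u]   # u -> parent v
        } else {
          tree$nodes$down_p[v] # parent u -> child v
        }
        if (is.na(p)) stop("edge probability not fitted")
        cross <- stats::runif(n) < p
        reached[, v] <- reached[, u] & cross
        queue <- c(queue, v)
      }
    }
    out <- reached[, tree$leaf_ids, drop = FALSE] * 1L
    colnames(out) <- tree$leaves
    out[, as.character(source)] <- 0L
    out
  })
}

#' Serialize a p-type tree
#'
#' Writes a JSON twin (lossless) and a Newick rendering whose branch
#' comments carry the two directed probabilities
#' (`[&up=<child-to-parent>,down=<parent-to-child>]`); branch lengths are
#' the up-edge lengths `-log10(up_p)`.
#'
#' @param tree a `ptype_tree`.
#' @param json_path,newick_path output paths (either may be `NULL`).
#' @return invisibly, the Newick string.
#' @export
write_ptype_tree <- function(tree, json_path = NULL, newick_path = NULL) {
  nwk <- paste0(newick_node(tree, tree$root), ";")
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(nodes = tree$nodes, epsilon = tree$epsilon),
                         json_path, dataframe = "columns", digits = NA,
                         na = "null")
  }
  invisible(nwk)
}

newick_node <- function(tree, id) {
  kids <- tree$nodes$id[!is.na(tree$nodes$parent) & tree$nodes$parent == id]
  lab <- if (tree$nodes$is_leaf[id]) tree$nodes$label[id] else ""
  body <- if (length(kids)) {
    paste0("(", paste(vapply(kids, function(k) newick_node(tree, k),
                             character(1)), collapse = ","), ")", lab)
  } else lab
  if (is.na(tree$nodes$parent[id])) return(body)
  up <- tree$nodes$up_p[id]; dn <- tree$nodes$down_p[id]
  if (is.na(up)) return(body)
  paste0(body, ":", format(-log10(up), digits = 10),
         "[&up=", format(up, digits = 10),
         ",down=", format(dn, digits = 10), "]")
}

#' @rdname write_ptype_tree
#' @param json_path path to a JSON twin written by [write_ptype_tree()].
#' @export
read_ptype_tree <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  nd <- obj$nodes
  ptype_tree(parent = nd$parent, leaf_label = nd$label,
             up_p = nd$up_p, down_p = nd$down_p, epsilon = obj$epsilon)
}
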