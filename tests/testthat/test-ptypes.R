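chain_tree <- function() {
  # S - R(0.8) - N(0.5) - {T1 (0.4), T2 (0.3)}
  ptype_tree(parent = c(5L, 6L, 6L, 5L, 7L, 7L, NA),
             leaf_label = c("S", "T1", "T2", "X", NA, NA, NA),
             up_p = c(0.8, 0.9, 0.7, 0.6, 1.0, 0.5, NA),
             down_p = c(0.8, 0.4, 0.3, 0.6, 0.9, 0.5, NA))
}

test_that("first-order innervation probability follows the class constants", {
  expect_equal(innervation_probability(0.04, "L2/3"), 0.1)
  expect_equal(innervation_probability(0.04, "L6"), 0.1)
  expect_equal(innervation_probability(0, "L4"), 0)
  expect_equal(innervation_probability(100, "L5IT"), 1)  # 2.2 clipped
  expect_equal(innervation_probability(1, "L5PT"), 0.33)
  expect_error(innervation_probability(1, "L23"), "unknown projection class")
  expect_error(innervation_probability(-1, "L6"), ">= 0")
})

test_that("path probabilities multiply edge probabilities along the path", {
  tr <- ptype_tree(parent = c(3L, 3L, NA), leaf_label = c("A", "B", NA),
                   up_p = c(0.5, 0.9, NA), down_p = c(0.7, 0.5, NA))
  expect_equal(path_probability(tr, "A", "B"), 0.25)  # 0.5 up, 0.5 down

  tr2 <- chain_tree()
  # S up (0.8), down into N (0.5), down into T1 (0.4)
  expect_equal(path_probability(tr2, "S", "T1"), 0.16)
  expect_error(path_probability(tr2, "S", "S"), "local connectivity")
  # a floor-probability edge bounds the product
  trf <- ptype_tree(parent = c(3L, 3L, NA), leaf_label = c("A", "B", NA),
                    up_p = c(1e-6, 1, NA), down_p = c(1, 1, NA))
  expect_lte(path_probability(trf, "A", "B"), 1e-6)
})

test_that("conditional increase equals the source-to-divergence path factor", {
  tr <- chain_tree()
  # increase for (T1, T2) from S: divergence at N; 1 / (0.8 * 0.5) = 2.5
  expect_equal(conditional_increase(tr, "S", "T1", "T2"), 2.5)
  # cross-check: P(T1 | T2) = P(both) / P(T2) = increase * P(T1)
  en <- enumerate_innervation(tr, "S")
  expect_equal(unname(en$joint["T1", "T2"] / en$marg["T2"]),
               2.5 * path_probability(tr, "S", "T1"), tolerance = 1e-12)
  expect_equal(conditional_increase(tr, "S", "T2", "T1"), 2.5)  # symmetry

  # edges from S to the divergence all certain -> independence
  tr1 <- ptype_tree(parent = c(5L, 6L, 6L, 5L, 7L, 7L, NA),
                    leaf_label = c("S", "T1", "T2", "X", NA, NA, NA),
                    up_p = c(1, 1, 1, 1, 1, 1, NA),
                    down_p = c(1, 0.4, 0.3, 1, 1, 1, NA))
  expect_equal(conditional_increase(tr1, "S", "T1", "T2"), 1)
})

test_that("closed forms match exhaustive enumeration on small trees", {
  for (seed in 1:10) {
    nl <- sample(3:6, 1)
    tr <- random_ptype_tree(nl, seed + 100)
    src <- tr$leaves[1]
    en <- enumerate_innervation(tr, src)
    for (tgt in setdiff(tr$leaves, src)) {
      expect_equal(path_probability(tr, src, tgt), unname(en$marg[tgt]),
                   tolerance = 1e-12)
    }
    others <- setdiff(tr$leaves, src)
    for (t1 in others) for (t2 in setdiff(others, t1)) {
      inc <- conditional_increase(tr, src, t1, t2)
      expect_gte(inc, 1 - 1e-12)
      cond <- unname(en$joint[t1, t2] / en$marg[t2])
      expect_equal(cond, unname(inc * en$marg[t1]), tolerance = 1e-12)
    }
  }
})

test_that("tree topology: trivial pair, planted blocks, determinism", {
  two <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  tr <- build_tree_topology(two, seed = 1)
  expect_length(tr$leaves, 2)
  expect_identical(nrow(tr$nodes), 3L)

  blk <- matrix(0.01, 8, 8, dimnames = list(paste0("R", 1:8),
                                            paste0("R", 1:8)))
  blk[1:4, 1:4] <- 1
  blk[5:8, 5:8] <- 1
  diag(blk) <- 0
  topo <- build_tree_topology(blk, seed = 1)
  # the two planted blocks sit in disjoint subtrees under the root
  root <- topo$root
  kids <- topo$nodes$id[!is.na(topo$nodes$parent) &
                          topo$nodes$parent == root]
  leaf_set <- function(id) {
    below <- id
    repeat {
      nxt <- topo$nodes$id[topo$nodes$parent %in% below &
                             !topo$nodes$id %in% below]
      if (!length(nxt)) break
      below <- c(below, nxt)
    }
    sort(topo$nodes$label[topo$nodes$id %in% below &
                            topo$nodes$is_leaf])
  }
  sets <- lapply(kids, leaf_set)
  expect_true(any(vapply(sets, function(s) {
    identical(s, paste0("R", 1:4)) || identical(s, paste0("R", 5:8))
  }, logical(1))))

  topo2 <- build_tree_topology(blk, seed = 1)
  expect_identical(topo$nodes, topo2$nodes)
  expect_error(build_tree_topology(matrix(numeric(0), 0, 0)), "empty")
})

test_that("edge-probability fitting recovers additive path lengths", {
  for (seed in 1:5) {
    tr <- random_ptype_tree(sample(5:12, 1), seed)
    L <- predicted_length_matrix(tr)
    skel <- ptype_tree(tr$nodes$parent, tr$nodes$label)
    fit <- fit_edge_probabilities(skel, L)
    expect_lt(max(abs(predicted_length_matrix(fit) - L)), 1e-6)
  }
})

test_that("motif least squares: symmetry and an independent minimizer", {
  # fully symmetric input (identical rows/columns): within the first
  # sibling motif all four solved weights are equal
  lv <- c("A", "B", "C", "D")
  M <- matrix(1, 4, 4, dimnames = list(lv, lv))
  diag(M) <- 0
  skel <- build_tree_topology(M + 0.1, seed = 2)
  fit <- fit_edge_probabilities(skel, M)
  first_inner <- min(fit$nodes$id[!fit$nodes$is_leaf])
  ch <- fit$nodes$id[!is.na(fit$nodes$parent) &
                       fit$nodes$parent == first_inner]
  w4 <- c(fit$nodes$up_p[ch], fit$nodes$down_p[ch])
  expect_lt(diff(range(-log10(w4))), 1e-9)

  # 3-leaf inconsistent instance: the solved motif attains the same
  # residual as a derivative-free minimizer of the same least squares
  lv3 <- c("A", "B", "C")
  set.seed(4)
  M3 <- matrix(runif(9, 0.2, 1.5), 3, 3, dimnames = list(lv3, lv3))
  diag(M3) <- 0
  skel3 <- ptype_tree(parent = c(4L, 4L, 5L, 5L, NA),
                      leaf_label = c("A", "B", "C", NA, NA))
  fit3 <- fit_edge_probabilities(skel3, M3)
  # reconstruct the first motif system (A, B siblings; C the reference)
  A <- rbind(c(1, -1, 0, 0), c(0, 0, 1, -1), c(1, 0, 0, 1), c(0, 1, 1, 0))
  b <- c(M3["A", "C"] - M3["B", "C"], M3["C", "A"] - M3["C", "B"],
         M3["A", "B"], M3["B", "A"])
  ls_fit <- optim(rep(0.5, 4), function(w) sum((A %*% w - b)^2),
                  method = "BFGS")
  wa <- c(fit3$nodes$up_p[1], fit3$nodes$up_p[2],
          fit3$nodes$down_p[1], fit3$nodes$down_p[2])
  expect_equal(sum((A %*% (-log10(wa)) - b)^2), ls_fit$value,
               tolerance = 1e-6)
})

test_that("sampled profiles match the closed-form marginals and pairs", {
  tr <- chain_tree()
  n <- 10000
  prof <- sample_innervation_profiles(tr, "S", n, seed = 11)
  expect_identical(dim(prof), c(10000L, 4L))
  expect_true(all(prof[, "S"] == 0))
  for (tgt in c("T1", "T2", "X")) {
    p <- path_probability(tr, "S", tgt)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(prof[, tgt]) - p), 3 * se)
  }
  # pairwise conditional increase within Monte-Carlo tolerance
  p2 <- mean(prof[, "T2"])
  cond <- mean(prof[prof[, "T2"] == 1, "T1"])
  inc_emp <- cond / mean(prof[, "T1"])
  expect_lt(abs(inc_emp - 2.5), 0.35)  # ~3 SE at these counts

  # degenerate limits
  all_on <- ptype_tree(parent = c(3L, 3L, NA), leaf_label = c("A", "B", NA),
                       up_p = 1, down_p = 1)
  expect_true(all(sample_innervation_profiles(all_on, "A", 50,
                                              seed = 1)[, "B"] == 1))
  # determinism
  expect_identical(sample_innervation_profiles(tr, "S", 100, seed = 3),
                   sample_innervation_profiles(tr, "S", 100, seed = 3))
})

test_that("hypergeometric independence test matches exact enumeration", {
  # N = 20, n_a = n_b = 10, overlap 10: p = 2 / choose(20, 10)
  mat <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  mat[1:10, "a"] <- 1
  mat[1:10, "b"] <- 1
  res <- test_pairwise_independence(mat, "a", "b")
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_true(res$reject)
  expect_equal(res$increase, 2)

  # overlap at expectation: no rejection
  mat2 <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  mat2[1:10, "a"] <- 1
  mat2[6:15, "b"] <- 1  # overlap 5 = 10 * 10 / 20
  res2 <- test_pairwise_independence(mat2, "a", "b")
  expect_false(res2$reject)
  expect_gt(res2$p_value, 0.5)

  mat3 <- matrix(0, 20, 2, dimnames = list(NULL, c("a", "b")))
  mat3[1:4, "b"] <- 1
  res3 <- test_pairwise_independence(mat3, "a", "b")
  expect_equal(res3$p_value, 1)
  expect_true(res3$flagged)
})

test_that("hamming distributions separate the tree model from the naive one", {
  tr <- chain_tree()
  prof <- sample_innervation_profiles(tr, "S", 2000, seed = 21)
  same <- compare_hamming_distributions(prof[1:1000, ], prof[1:1000, ])
  expect_equal(same$ks_statistic, 0)

  p1 <- vapply(setdiff(tr$leaves, "S"), function(tgt) {
    path_probability(tr, "S", tgt)
  }, numeric(1))
  p1 <- c(p1, S = 0)[colnames(prof)]
  names(p1) <- colnames(prof)
  naive <- sample_naive_profiles(p1, 2000, seed = 22)
  cmp <- compare_hamming_distributions(prof, naive)
  # shared-path correlations widen the tree model's distance distribution
  expect_gt(stats::var(cmp$dist_a), stats::var(cmp$dist_b))
  expect_error(compare_hamming_distributions(prof[1, , drop = FALSE], naive),
               "at least 2")
})

test_that("trees serialize to JSON/Newick and round-trip losslessly", {
  tr <- random_ptype_tree(6, 3)
  jp <- tempfile(fileext = ".json")
  np <- tempfile(fileext = ".nwk")
  nwk <- write_ptype_tree(tr, jp, np)
  expect_true(grepl("^\\(", nwk))
  expect_true(grepl("&up=", readLines(np)[1]))
  tr2 <- read_ptype_tree(jp)
  expect_equal(tr2$nodes$up_p, tr$nodes$up_p, tolerance = 1e-9)
  expect_identical(tr2$leaves, tr$leaves)
  expect_equal(predicted_length_matrix(tr2), predicted_length_matrix(tr),
               tolerance = 1e-9)
})
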