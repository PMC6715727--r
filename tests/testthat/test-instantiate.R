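test_that("greedy allocation hits fractions and enforced overlaps", {
  pop <- 1:1000
  all_in <- allocate_source_neurons(pop, c(p1 = 1, p2 = 1), seed = 1)
  expect_setequal(all_in$p1, pop)
  expect_setequal(all_in$p2, pop)

  # f = 0.5 each with interaction 2.0: the two sets must coincide
  al <- allocate_source_neurons(pop, c(p1 = 0.5, p2 = 0.5),
                                data.frame(a = "p1", b = "p2",
                                           increase = 2), seed = 2)
  expect_identical(length(al$p1), 500L)
  expect_identical(length(al$p2), 500L)
  expect_gte(length(intersect(al$p1, al$p2)), 500L)

  # without interactions the overlap follows independence
  big <- 1:10000
  al2 <- allocate_source_neurons(big, c(p1 = 0.3, p2 = 0.3), seed = 3)
  ov <- length(intersect(al2$p1, al2$p2))
  se <- sqrt(10000 * 0.09 * 0.91)
  expect_lt(abs(ov - 900), 3 * se)

  expect_error(
    allocate_source_neurons(pop, c(p1 = 0.2, p2 = 0.2),
                            data.frame(a = "p1", b = "p2", increase = 10)),
    "infeasible overlap.*p1, p2")
  expect_error(allocate_source_neurons(integer(), c(p = 1)), "empty")
})

test_that("synapse counts follow density, profile and thickness weighting", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas

  z <- projection_synapse_counts(0, atlas, 2, seed = 1)
  expect_identical(sum(z$count), 0L)

  # flat profile: expected total = density x volume, expectation exact
  d <- 1e-5
  cnt <- projection_synapse_counts(d, atlas, 2, seed = 2)
  vol <- atlas$region_volumes[["2"]]
  expect_equal(attr(cnt, "expected_total"), d * vol)
  expect_equal(sum(cnt$expected), d * vol, tolerance = 1e-9)
  expect_lt(abs(sum(cnt$count) - d * vol), 3 * sqrt(d * vol))

  # profile (2, 0, ...) with equal thicknesses: everything in layer 1
  prof <- c(2, rep(0, atlas$n_layers - 1))
  cnt2 <- projection_synapse_counts(d, atlas, 2, layer_profile = prof,
                                    seed = 3)
  expect_true(all(cnt2$count[cnt2$layer != 1] == 0))
  expect_gt(sum(cnt2$count[cnt2$layer == 1]), 0)

  expect_warning(
    e <- projection_synapse_counts(1, atlas, 2,
                                   voxels = region_voxels(atlas, 2)[0, ]),
    "empty target")
  expect_identical(nrow(e), 0L)
})

test_that("synapse placement weights segments by length", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  cells <- synth_neurons_and_segments(atlas, fm, neurons_per_voxel = 0.5,
                                      seed = 4)
  segs <- cells$segments[cells$segments$region == 2, ]
  cnt <- projection_synapse_counts(2e-5, atlas, 2, seed = 5)
  syn <- sample_synapse_positions(cnt, segs, atlas, seed = 6)
  expect_identical(nrow(syn), sum(cnt$count))
  expect_true(all(syn$offset >= 0 & syn$offset <= 1))
  expect_true(all(syn$segment_id %in% segs$id))

  # two segments, lengths 1 and 3, in one voxel: counts split 1:3
  one_vox <- cnt[which(cnt$count > 0)[1], , drop = FALSE]
  one_vox$count <- 4000L
  vs <- atlas$voxel_size
  two_segs <- data.frame(
    id = 1:2, neuron_id = 1:2, region = 2, layer = one_vox$layer,
    x = (one_vox$i - 0.5) * vs, y = (one_vox$j - 0.5) * vs,
    z = (one_vox$k - 0.5) * vs,
    flat_x = (one_vox$i - 0.5) * vs, flat_y = (one_vox$j - 0.5) * vs,
    length = c(1, 3))
  syn2 <- sample_synapse_positions(one_vox, two_segs, atlas, seed = 7)
  n1 <- sum(syn2$segment_id == 1)
  se <- sqrt(4000 * 0.25 * 0.75)
  expect_lt(abs(n1 - 1000), 3 * se)

  # empty counts give an empty table
  empty <- cnt[0, ]
  expect_identical(nrow(sample_synapse_positions(empty, segs, atlas)), 0L)
})

test_that("presynaptic assignment follows the Gaussian mapping kernel", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  src_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 1))
  tgt_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 2))
  mp <- topo_mapping(src_sys, tgt_sys, kernel_width = 150)

  syn <- data.frame(segment_id = 1, target_neuron = 99, region = 2,
                    layer = 2, x = 0, y = 0, z = 0,
                    flat_x = tgt_sys$anchors[1, 1],
                    flat_y = tgt_sys$anchors[1, 2],
                    offset = 0.5)
  syn <- syn[rep(1, 4000), ]

  # a single allocated source takes every synapse
  neurons <- data.frame(id = 1:2,
                        flat_x = src_sys$anchors[1:2, 1],
                        flat_y = src_sys$anchors[1:2, 2])
  tab1 <- assign_presynaptic_neurons(syn, 1, neurons, mp, seed = 1)
  expect_true(all(tab1$source_neuron == 1))

  # two sources at mapped distances 0 and d: ratio exp(-d^2 / (2 sigma^2))
  # source 1 maps exactly onto the synapse pixel (anchor 1); source 2 to
  # anchor 2, at distance d
  tab2 <- assign_presynaptic_neurons(syn, c(1, 2), neurons, mp, seed = 2)
  d <- sqrt(sum((tgt_sys$anchors[1, ] - tgt_sys$anchors[2, ])^2))
  w2 <- exp(-d^2 / (2 * 150^2))
  p1 <- 1 / (1 + w2)
  n1 <- sum(tab2$source_neuron == 1)
  se <- sqrt(4000 * p1 * (1 - p1))
  expect_lt(abs(n1 - 4000 * p1), 3 * se)

  expect_error(assign_presynaptic_neurons(syn, integer(), neurons, mp),
               "empty allocated source")
})

test_that("projection classes follow morphology and the thick-tufted coin", {
  n <- 10000
  neurons <- data.frame(id = 1:n, mtype = "L5_TPC", layer = 5)
  cls <- assign_projection_classes(neurons, seed = 1)
  n_pt <- sum(cls == "L5PT", na.rm = TRUE)
  se <- sqrt(n * 0.25)
  expect_lt(abs(n_pt - n / 2), 3 * se)
  expect_true(all(is.na(cls) | cls == "L5PT"))

  mix <- data.frame(id = 1:5,
                    mtype = c("PC", "PC", "INT", "L5_STPC", "L5_UPC"),
                    layer = c(4, 6, 3, 5, 5))
  cmix <- assign_projection_classes(mix, seed = 2)
  expect_identical(cmix, c("L4", "L6", NA, "L5IT", "L5IT"))
  expect_warning(assign_projection_classes(
    data.frame(id = 1, mtype = "weird", layer = 2)), "unknown")
})

test_that("edge output round-trips and marginals match synapse counts", {
  set.seed(8)
  tab <- structure(data.frame(
    source_neuron = sample(1:20, 500, replace = TRUE),
    target_neuron = sample(21:50, 500, replace = TRUE),
    segment_id = sample(1:100, 500, replace = TRUE),
    offset = runif(500), x = runif(500), y = runif(500), z = runif(500),
    region = sample(c(2L, 4L), 500, replace = TRUE)),
    class = c("synapse_table", "data.frame"))
  d <- tempfile()
  write_edge_output(tab, d, n_neurons = 50)
  rt <- read_edge_output(d)
  expect_equal(rt$edges$source_node_id, tab$source_neuron)
  expect_equal(rt$edges$offset, tab$offset)
  expect_identical(rt$meta$n_edges, 500L)

  # sparse-matrix marginals equal per-neuron synapse counts per region
  for (r in c("2", "4")) {
    sub <- tab[tab$region == as.integer(r), ]
    m <- rt$matrices[[r]]
    expect_equal(sum(m), nrow(sub))
    out_counts <- table(factor(sub$source_neuron, levels = 1:50))
    expect_equal(unname(Matrix::rowSums(m)), as.numeric(out_counts))
    in_counts <- table(factor(sub$target_neuron, levels = 1:50))
    expect_equal(unname(Matrix::colSums(m)), as.numeric(in_counts))
  }

  # empty table still writes a valid zero-edge file
  d2 <- tempfile()
  write_edge_output(tab[0, ], d2, n_neurons = 5)
  rt2 <- read_edge_output(d2)
  expect_identical(nrow(rt2$edges), 0L)
})

test_that("instantiation is deterministic for a fixed seed", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  cells <- synth_neurons_and_segments(atlas, fm, neurons_per_voxel = 0.3,
                                      seed = 9)
  segs <- cells$segments[cells$segments$region == 2, ]
  src_ids <- cells$neurons$id[cells$neurons$region == 1][1:30]
  mp <- topo_mapping(fit_source_anchors(region_flat_mask(atlas, fm, 1)),
                     fit_source_anchors(region_flat_mask(atlas, fm, 2)),
                     kernel_width = 120)
  run <- function() {
    cnt <- projection_synapse_counts(5e-6, atlas, 2, seed = 10)
    syn <- sample_synapse_positions(cnt, segs, atlas, seed = 11)
    assign_presynaptic_neurons(syn, src_ids, cells$neurons, mp, seed = 12)
  }
  expect_identical(run(), run())
})
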