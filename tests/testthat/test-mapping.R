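square_mask <- function(n = 10, px = 100) {
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  g <- g[order(g$i, g$j), ]
  data.frame(i = g$i, j = g$j, x = (g$i - 0.5) * px, y = (g$j - 0.5) * px)
}

test_that("barycentric systems are affine and invertible", {
  sys <- bary_system(rbind(c(0, 0), c(100, 0), c(0, 100)))
  b <- to_bary(sys, sys$anchors)
  expect_equal(b, diag(3), tolerance = 1e-12)
  pts <- rbind(c(10, 20), c(-50, 30), c(200, 200))
  expect_equal(rowSums(to_bary(sys, pts)), rep(1, 3), tolerance = 1e-12)
  expect_equal(from_bary(sys, to_bary(sys, pts)), unname(pts),
               tolerance = 1e-9)
  expect_error(bary_system(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("source anchors maximize spread then shrink toward the centroid", {
  # equilateral triangle of pixels: its vertices, shrunk 25%
  tri <- rbind(c(0, 0), c(400, 0), c(200, 400 * sqrt(3) / 2))
  fill <- rbind(tri, c(200, 115), c(150, 100), c(250, 100))
  mask <- data.frame(x = fill[, 1], y = fill[, 2])
  sys <- fit_source_anchors(mask)
  centroid <- colMeans(fill)
  expected <- tri + 0.25 * (matrix(centroid, 3, 2, byrow = TRUE) - tri)
  perm <- apply(sys$anchors, 1, function(a) {
    which.min(colSums((t(expected) - a)^2))
  })
  expect_identical(sort(perm), 1:3)
  expect_equal(unname(sys$anchors[order(perm), ]),
               unname(expected[sort(perm), ]), tolerance = 1e-9)

  # hull-restricted search equals exhaustive search on a square mask
  mask2 <- square_mask(6)
  h <- fit_source_anchors(mask2, use_hull = TRUE)
  e <- fit_source_anchors(mask2, use_hull = FALSE)
  expect_equal(h$anchors, e$anchors, tolerance = 1e-9)

  expect_error(fit_source_anchors(square_mask(6)[1:2, ]), "fewer than 3")
})

test_that("rendering colors pixels by source bary coordinates and strength", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  src_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 1))
  tgt_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 2))
  planted <- topo_mapping(src_sys, tgt_sys, kernel_width = 80)
  tens <- synth_projection_tensor(atlas, fm, planted, 1, 2)

  zero <- tens
  zero$strengths[] <- 0
  img0 <- render_projection_image(zero, src_sys)
  expect_true(all(img0$raw == 0))

  img <- render_projection_image(tens, src_sys)
  expect_true(all(img$raw >= 0))
  expect_equal(max(rowSums(img$raw)), 1)  # lightness scale convention

  # a voxel at the anchor-triangle centroid has saturation 0 (< 0.5)
  # and contributes nothing
  ctr_pt <- colMeans(src_sys$anchors)
  sat <- corticonn:::rgb_saturation(
    corticonn:::bary_colors(src_sys, matrix(ctr_pt, 1, 2)))
  expect_lt(sat, 0.5)
  one <- tens
  one$strengths[] <- 0
  one$source_voxels$x[1] <- ctr_pt[1]
  one$source_voxels$y[1] <- ctr_pt[2]
  one$strengths[1, ] <- 5
  img1 <- render_projection_image(one, src_sys)
  expect_true(all(img1$raw == 0))

  # a voxel exactly at anchor 1 renders pure red at its target pixel
  a1 <- src_sys$anchors[1, ]
  vi <- which.min((tens$source_voxels$x - a1[1])^2 +
                    (tens$source_voxels$y - a1[2])^2)
  two <- tens
  two$strengths[] <- 0
  two$strengths[vi, 7] <- 3
  col <- corticonn:::bary_colors(
    src_sys, matrix(as.numeric(tens$source_voxels[vi, c("x", "y")]), 1, 2))
  img2 <- render_projection_image(two, src_sys)
  expect_equal(unname(img2$raw[7, ] / sum(img2$raw[7, ])),
               as.numeric(col / sum(col)), tolerance = 1e-9)
  expect_true(all(img2$raw[-7, ] == 0))
})

test_that("image normalization floors the denominator at a quarter of max", {
  px <- data.frame(i = 1:2, j = c(1, 1), x = c(50, 150), y = c(50, 50))
  img <- structure(list(
    raw = rbind(c(0.2, 0.1, 0.1), c(0.5, 0.3, 0.2)), pixels = px,
    lightness_scale = 1, saturation_threshold = 0.5),
    class = "projection_image")
  # max channel sum is 1.0 -> sigma 0.25; pixel 1 sum 0.4 >= sigma
  nrm <- normalize_image(img)
  expect_equal(nrm$sigma_tgt, 0.25)
  expect_equal(nrm$colors[1, ], c(0.5, 0.25, 0.25))
  expect_equal(sum(nrm$colors[2, ]), 1)

  # dim pixel: divided by sigma, fades toward black
  img$raw[1, ] <- c(0.02, 0.01, 0.01)
  nrm2 <- normalize_image(img)
  expect_equal(nrm2$colors[1, ], c(0.08, 0.04, 0.04))
  expect_lt(sum(nrm2$colors[1, ]), 1)
  # normalization invariant: channel sums never exceed 1
  expect_true(all(rowSums(nrm2$colors) <= 1 + 1e-9))

  img$raw[] <- 0
  expect_warning(nrm3 <- normalize_image(img), "all-black")
  expect_true(all(nrm3$colors == 0))
})

test_that("relative image error matches hand computation and is symmetric", {
  M <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_identical(mapping_relative_error(M, M), 0)
  N <- rbind(c(0.5, 0.5, 0), c(0, 1, 0))
  # sum |M-N| = 1; average value = (2 + 2) / 2 / 6 = 1/3; pixels = 2
  expect_equal(mapping_relative_error(M, N), 1 / (1 / 3) / 2)
  expect_equal(mapping_relative_error(M, N), mapping_relative_error(N, M))
})

test_that("mapped points preserve barycentric coordinates", {
  s <- bary_system(rbind(c(0, 0), c(100, 0), c(0, 100)))
  t <- bary_system(rbind(c(500, 500), c(500, 700), c(300, 500)))
  mp <- topo_mapping(s, t, kernel_width = 30)
  expect_equal(map_source_to_target(s$anchors, mp)$point,
               unname(t$anchors), tolerance = 1e-9)
  expect_equal(map_source_to_target(matrix(colMeans(s$anchors), 1, 2),
                                    mp)$point[1, ],
               colMeans(t$anchors), tolerance = 1e-9)
  # equals the unique affine transform taking source anchors to target
  X <- cbind(s$anchors, 1)
  beta <- solve(X, t$anchors)
  pts <- rbind(c(13, 27), c(-40, 80), c(120, 140))
  expect_equal(map_source_to_target(pts, mp)$point,
               cbind(pts, 1) %*% beta, tolerance = 1e-9)
  expect_equal(map_source_to_target(pts, mp)$kernel_width, 30)

  # round trip through the reversed mapping is the identity
  back <- map_source_to_target(map_source_to_target(pts, mp)$point,
                               reverse_mapping(mp))$point
  expect_equal(back, unname(pts), tolerance = 1e-9)
})

test_that("transform characterization detects reflections and rotations", {
  s <- bary_system(rbind(c(0, 0), c(100, 0), c(20, 90)))
  idt <- characterize_transform(topo_mapping(s, s))
  expect_false(idt$reflection)
  expect_identical(idt$rotation, 0)

  mirror <- bary_system(s$anchors %*% diag(c(-1, 1)))
  m <- characterize_transform(topo_mapping(s, mirror))
  expect_true(m$reflection)

  a <- pi / 2
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  rot <- bary_system(s$anchors %*% t(R))
  r <- characterize_transform(topo_mapping(s, rot))
  expect_false(r$reflection)
  expect_identical(r$rotation, 90)

  rotm <- bary_system(s$anchors %*% t(R %*% diag(c(-1, 1))))
  rm_ <- characterize_transform(topo_mapping(s, rotm))
  expect_true(rm_$reflection)
  expect_identical(rm_$rotation, 90)
})

test_that("kernel width recovery is grid-consistent and monotone", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  src_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 1))
  tgt_sys <- fit_source_anchors(region_flat_mask(atlas, fm, 2))
  widths <- c(0, 100 * 2^seq(-1, 3, by = 0.5))
  rec <- vapply(c(55, 105, 210), function(w0) {
    planted <- topo_mapping(src_sys, tgt_sys, kernel_width = w0)
    tens <- synth_projection_tensor(atlas, fm, planted, 1, 2)
    norm <- normalize_image(render_projection_image(tens, src_sys))
    as.numeric(fit_kernel_width(norm, planted, widths = widths,
                                pixel_size = fm$pixel_size))
  }, numeric(1))
  # recovered within one grid step of the planted width
  for (k in seq_along(rec)) {
    gi <- which.min(abs(widths - c(55, 105, 210)[k]))
    expect_lte(abs(which(widths == rec[k]) - gi), 1)
  }
  # more planted blur never gives a smaller recovered width
  expect_true(all(diff(rec) >= 0))
})

test_that("planted mappings are recovered by the full fitting pipeline", {
  ab <- build_synthetic_atlas()
  atlas <- ab$atlas; fm <- ab$flatmap
  src_mask <- region_flat_mask(atlas, fm, 1)
  tgt_mask <- region_flat_mask(atlas, fm, 2)
  src_sys <- fit_source_anchors(src_mask)
  sc <- colMeans(as.matrix(src_mask[, c("x", "y")]))
  tc <- colMeans(as.matrix(tgt_mask[, c("x", "y")]))

  # identity-geometry fixture
  planted <- topo_mapping(src_sys, bary_system(
    sweep(sweep(src_sys$anchors, 2, sc), 2, tc, "+")), kernel_width = 60)
  tens <- synth_projection_tensor(atlas, fm, planted, 1, 2)
  mp <- fit_topographic_mapping(tens, atlas, fm, seed = 1)
  expect_lt(max(sqrt(rowSums(
    (mp$target$anchors - planted$target$anchors)^2))), fm$pixel_size)
  expect_lt(mp$fit_error, 0.02)
  tr <- characterize_transform(mp)
  expect_false(tr$reflection)
  expect_identical(tr$rotation, 0)

  # reflected fixture reproduces the reflection
  refl_anch <- sweep(sweep(src_sys$anchors, 2, sc) %*% diag(c(-1, 1)),
                     2, tc, "+")
  planted_r <- topo_mapping(src_sys, bary_system(refl_anch),
                            kernel_width = 60)
  tens_r <- synth_projection_tensor(atlas, fm, planted_r, 1, 2)
  mp_r <- fit_topographic_mapping(tens_r, atlas, fm, seed = 1)
  expect_lt(max(sqrt(rowSums((mp_r$target$anchors - refl_anch)^2))),
            fm$pixel_size)
  expect_true(characterize_transform(mp_r)$reflection)
})
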