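#' Topographic mapping between two flattened regions
#'
#' A pair of barycentric systems — one in the flattened source region, one
#' in the target — defines the mapping: a source point is mapped to the
#' target point with identical barycentric coordinates. Because projection
#' axons innervate an area rather than a point, each mapped point carries a
#' 2-D Gaussian kernel of width `kernel_width`.
#'
#' @param source,target `bary_system` objects.
#' @param kernel_width Gaussian kernel width in micrometers (>= 0).
#' @param fit_error relative fit error (NA until fitted).
#' @return object of class `topo_mapping`.
#' @export
topo_mapping <- function(source, target, kernel_width = 0, fit_error = NA_real_) {
  stopifnot(inherits(source, "bary_system"), inherits(target, "bary_system"),
            kernel_width >= 0)
  structure(list(source = source, target = target,
                 kernel_width = kernel_width, fit_error = fit_error),
            class = "topo_mapping")
}

#' @export
print.topo_mapping <- function(x, ...) {
  cat("Topographic mapping; kernel width", signif(x$kernel_width, 4), "um")
  if (!is.na(x$fit_error)) cat("; relative fit error", signif(x$fit_error, 3))
  cat("\n")
  tr <- characterize_transform(x)
  cat("  transform: reflection", ifelse(tr$reflection, "yes", "no"),
      "| rotation", tr$rotation, "deg\n")
  invisible(x)
}

#' Map source points into the target region
#'
#' Barycentric coordinates are preserved; points outside the source anchor
#' triangle extrapolate (coordinates may be negative).
#'
#' @param points n x 2 matrix of flat source coordinates (um).
#' @param mapping a `topo_mapping`.
#' @return list with `point` (n x 2 mapped coordinates) and `kernel_width`.
#' @export
map_source_to_target <- function(points, mapping) {
  b <- to_bary(mapping$source, points)
  list(point = from_bary(mapping$target, b),
       kernel_width = mapping$kernel_width)
}

#' Reverse a topographic mapping
#' @param mapping a `topo_mapping`.
#' @return the mapping with source and target systems swapped.
#' @export
reverse_mapping <- function(mapping) {
  topo_mapping(mapping$target, mapping$source, mapping$kernel_width,
               mapping$fit_error)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# HSV-style saturation of RGB rows
rgb_saturation <- function(rgb) {
  mx <- do.call(pmax, as.data.frame(rgb))
  mn <- do.call(pmin, as.data.frame(rgb))
  ifelse(mx > 0, 1 - mn / mx, 0)
}

# anchor-induced coloring: clamped barycentric coordinates as RGB
bary_colors <- function(sys, pts) {
  clamp01(to_bary(sys, pts))
}

#' Render the projection image of a tensor
#'
#' Each source voxel is colored by its barycentric coordinates in the
#' source system (channel i = coordinate i, clamped to `[0, 1]`), and each
#' target pixel accumulates color weighted by the 2-D-projected projection
#' strength it receives from each source voxel. Source voxels whose color
#' saturation falls below the threshold contribute nothing. The lightness
#' scale `f` is chosen so the brightest pixel has channel sum 1.
#'
#' @param tensor a `projection_tensor`.
#' @param src_system `bary_system` in the flattened source region.
#' @param saturation_threshold minimum source-voxel color saturation
#'   (default 0.5).
#' @return object of class `projection_image` with fields `raw`
#'   (pixels x 3), `pixels`, `lightness_scale`.
#' @export
render_projection_image <- function(tensor, src_system,
                                    saturation_threshold = 0.5) {
  B <- bary_colors(src_system, as.matrix(tensor$source_voxels[, c("x", "y")]))
  sat <- rgb_saturation(B)
  B[sat < saturation_threshold, ] <- 0
  raw <- t(tensor$strengths) %*% B  # pixels x 3
  f <- {
    m <- max(rowSums(raw))
    if (m > 0) 1 / m else 1
  }
  structure(list(raw = raw * f, pixels = tensor$target_pixels,
                 lightness_scale = f,
                 saturation_threshold = saturation_threshold),
            class = "projection_image")
}

#' Normalize a projection image
#'
#' Divides each pixel by the total projection strength reaching it, with
#' the denominator floored at `sigma_tgt`, 25% of the maximum per-pixel
#' channel sum, so weakly innervated parts of the target fade to black
#' instead of being amplified.
#'
#' @param img a `projection_image`.
#' @return object of class `normalized_image` with fields `pixels`,
#'   `colors` (pixels x 3), `sigma_tgt`, `bright` (logical: channel sum
#'   reached `sigma_tgt`).
#' @export
normalize_image <- function(img) {
  sums <- rowSums(img$raw)
  mx <- max(sums)
  if (mx <= 0) {
    warning("all-black projection image; returning black")
    return(structure(list(pixels = img$pixels, colors = img$raw,
                          sigma_tgt = 0, bright = rep(FALSE, nrow(img$raw))),
                     class = "normalized_image"))
  }
  sigma <- 0.25 * mx
  colors <- img$raw / pmax(sums, sigma)
  structure(list(pixels = img$pixels, colors = colors, sigma_tgt = sigma,
                 bright = sums >= sigma),
            class = "normalized_image")
}

#' Relative difference between two colored images
#'
#' The sum of absolute differences of the two images, divided by their
#' average value and by the number of pixels. Zero iff identical;
#' symmetric in its arguments.
#'
#' @param M,N numeric matrices of identical shape (pixels x channels).
#' @return non-negative scalar.
#' @export
mapping_relative_error <- function(M, N) {
  M <- as.matrix(M); N <- as.matrix(N)
  stopifnot(all(dim(M) == dim(N)))
  avg <- mean((M + N) / 2)
  if (avg == 0) return(0)
  sum(abs(M - N)) / avg / nrow(M)
}

#' Fit target anchors to a normalized projection image
#'
#' Optimizes the three target anchor points so the anchor-induced coloring
#' of the target region recreates the color scheme of the normalized
#' image. The objective is the mean per-pixel L1 color difference over
#' reliably innervated pixels (those whose raw channel sum reached the
#' normalization floor; faded pixels carry no reliable color) plus
#' `lambda` times the fraction of the source region mapped outside the
#' target region. Derivative-free (Nelder-Mead) with multi-start: the
#' restarts initialize the target triangle at the eight canonical
#' orthogonal placements (four rotations, with and without reflection) of
#' the source-anchor geometry in the target mask.
#'
#' @param norm a `normalized_image` of the projection.
#' @param target_mask flat mask of the target region
#'   (see [region_flat_mask()]).
#' @param source_mask flat mask of the source region.
#' @param src_system the source `bary_system`.
#' @param lambda weight of the out-of-region penalty (default 1).
#' @param n_restarts number of seeded restarts (default 8).
#' @param seed integer seed for restart perturbations.
#' @param pixel_size pixel size in micrometers (for the outside test).
#' @return a `topo_mapping` with fitted target anchors, `fit_error` (the
#'   relative error over reliable pixels), and attributes `objective` and
#'   `converged`.
#' @export
fit_target_anchors <- function(norm, target_mask, source_mask, src_system,
                               lambda = 1, n_restarts = 8, seed = 0,
                               pixel_size = NULL) {
  if (nrow(target_mask) == 0) stop("empty target mask")
  tgt_pts <- as.matrix(target_mask[, c("x", "y")])
  src_pts <- as.matrix(source_mask[, c("x", "y")])
  if (is.null(pixel_size)) {
    pixel_size <- min(dist(tgt_pts[seq_len(min(40, nrow(tgt_pts))), ]))
  }
  use <- norm$bright
  if (!any(use)) stop("no reliably innervated pixels to fit against")
  Nc <- norm$colors[use, , drop = FALSE]
  fit_pts <- as.matrix(norm$pixels[use, c("x", "y")])
  src_bary <- to_bary(src_system, src_pts)

  objective <- function(par) {
    anchors <- matrix(par, 3, 2)
    if (abs(signed_area2(anchors)) < 1e-6) return(1e6)
    sys <- bary_system(anchors)
    Mc <- bary_colors(sys, fit_pts)
    color_term <- mean(rowSums(abs(Mc - Nc)))
    mapped <- src_bary %*% anchors
    d2 <- outer(mapped[, 1], tgt_pts[, 1], "-")^2 +
      outer(mapped[, 2], tgt_pts[, 2], "-")^2
    outside <- sqrt(apply(d2, 1, min)) > 0.75 * pixel_size
    color_term + lambda * mean(outside)
  }

  src_anch <- src_system$anchors
  src_c <- colMeans(src_pts)
  tgt_c <- colMeans(tgt_pts)
  scale_ratio <- sqrt(mean(rowSums(sweep(tgt_pts, 2, tgt_c)^2)) /
                        mean(rowSums(sweep(src_pts, 2, src_c)^2)))
  inits <- list()
  for (refl in c(FALSE, TRUE)) {
    for (ang in c(0, 90, 180, 270) * pi / 180) {
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      G <- if (refl) R %*% diag(c(-1, 1)) else R
      a <- sweep(src_anch, 2, src_c) %*% t(G) * scale_ratio
      inits[[length(inits) + 1L]] <- sweep(a, 2, tgt_c, "+")
    }
  }
  inits <- inits[seq_len(min(n_restarts, length(inits)))]
  if (n_restarts > length(inits)) {
    extra <- local_seed(seed, {
      lapply(seq_len(n_restarts - length(inits)), function(i) {
        inits[[1 + (i - 1) %% 8]] +
          matrix(stats::rnorm(6, 0, pixel_size), 3, 2)
      })
    })
    inits <- c(inits, extra)
  }

  best <- NULL
  for (a0 in inits) {
    fit <- stats::optim(as.numeric(a0), objective, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  anchors <- matrix(best$par, 3, 2)
  mp <- topo_mapping(src_system, bary_system(anchors))
  Mc <- bary_colors(mp$target, fit_pts)
  mp$fit_error <- mapping_relative_error(Mc, Nc)
  attr(mp, "objective") <- best$value
  attr(mp, "converged") <- best$convergence == 0
  mp
}

#' Fit the Gaussian kernel width of a mapping
#'
#' The width is chosen on a logarithmic grid to minimize the
#' Kolmogorov-Smirnov distance between the distribution of color
#' saturation values of the (Gaussian-convolved) anchor-induced target
#' coloring and that of the normalized data image, over reliable pixels.
#'
#' @param norm a `normalized_image`.
#' @param mapping a `topo_mapping` with fitted target anchors.
#' @param widths candidate widths in micrometers; default 0 plus a log
#'   grid from half a pixel to eight pixels.
#' @param pixel_size pixel size in micrometers.
#' @return the selected width (um), with the KS profile as attribute.
#' @export
fit_kernel_width <- function(norm, mapping, widths = NULL,
                             pixel_size = NULL) {
  pts <- as.matrix(norm$pixels[, c("x", "y")])
  if (is.null(pixel_size)) {
    pixel_size <- sqrt(min(dist(pts[seq_len(min(40, nrow(pts))), ])^2))
  }
  if (is.null(widths)) {
    widths <- c(0, pixel_size * 2^seq(-1, 3, by = 0.5))
  }
  use <- norm$bright
  target_sat <- rgb_saturation(norm$colors[use, , drop = FALSE])
  base_col <- bary_colors(mapping$target, pts)
  D2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  ks <- vapply(widths, function(w) {
    col <- if (w <= 0) base_col else {
      K <- exp(-D2 / (2 * w^2))
      (K %*% base_col) / rowSums(K)
    }
    s <- rgb_saturation(col[use, , drop = FALSE])
    ks_distance(s, target_sat)
  }, numeric(1))
  out <- widths[which.min(ks)]
  attr(out, "ks") <- data.frame(width = widths, ks = ks)
  out
}

# two-sample KS statistic (distance only; no ties warning)
ks_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  w <- c(a, b)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n, 1 / n, -1 / m))
  max(abs(z))
}

#' Reflection and rotation character of a mapping
#'
#' Compares the linear part of the affine transform taking the source
#' anchors to the target anchors: the mapping contains a reflection iff
#' the signed area of the anchor triangle flips sign, and its rotation is
#' the nearest multiple of 90 degrees of the rotation component of the
#' best-fit similarity transform (reflection factored out as a flip of the
#' first axis).
#'
#' @param mapping a `topo_mapping`.
#' @return list with `reflection` (logical) and `rotation` (0, 90, 180 or
#'   270 degrees).
#' @export
characterize_transform <- function(mapping) {
  s <- mapping$source$anchors
  t <- mapping$target$anchors
  X <- cbind(s, 1)
  beta <- solve(X, t)      # 3 x 2; rows 1:2 = linear part (transposed)
  L <- t(beta[1:2, , drop = FALSE])
  if (abs(det(L)) < 1e-12) stop("degenerate anchor transform")
  reflection <- sign(signed_area2(t)) != sign(signed_area2(s))
  B <- if (reflection) L %*% diag(c(-1, 1)) else L
  theta <- atan2(B[2, 1] - B[1, 2], B[1, 1] + B[2, 2])
  rot <- (round(theta / (pi / 2)) %% 4) * 90
  list(reflection = reflection, rotation = unname(rot))
}

#' Pipeline-level relative error of a fitted mapping
#'
#' Renders the projection image that the fitted mapping itself would
#' generate (an ideal noise-free tensor with the fitted anchors and kernel
#' width, pushed through the same render-and-normalize pipeline) and
#' compares it with the normalized data image using
#' [mapping_relative_error()]. A perfect fit scores 0.
#'
#' @param mapping a fitted `topo_mapping` (kernel width set).
#' @param tensor the data `projection_tensor` the mapping was fitted to.
#' @param atlas,flatmap atlas and flat map.
#' @param src_system the source `bary_system` used for rendering.
#' @return non-negative scalar relative error.
#' @export
mapping_pipeline_error <- function(mapping, tensor, atlas, flatmap,
                                   src_system = mapping$source) {
  ideal <- synth_projection_tensor(atlas, flatmap, mapping,
                                   tensor$source_region,
                                   tensor$target_region,
                                   base_strength = 1, noise_sd = 0,
                                   check_anchors = FALSE)
  model_norm <- normalize_image(render_projection_image(ideal, src_system))
  data_norm <- normalize_image(render_projection_image(tensor, src_system))
  mapping_relative_error(model_norm$colors, data_norm$colors)
}

#' Refine a fitted mapping against the pipeline error
#'
#' Joint derivative-free refinement of the three target anchors and the
#' kernel width, minimizing the pipeline-level relative error (the
#' difference between the image the mapping itself generates and the
#' normalized data image). Used as a polish step after the coarse
#' color-matching fit and the grid search for the kernel width.
#'
#' @param mapping a fitted `topo_mapping` (starting point).
#' @param tensor the data `projection_tensor`.
#' @param atlas,flatmap atlas and flat map.
#' @param src_system source `bary_system`.
#' @param maxit Nelder-Mead iteration cap.
#' @return the refined `topo_mapping` with `fit_error` updated.
#' @export
polish_mapping <- function(mapping, tensor, atlas, flatmap,
                           src_system = mapping$source, maxit = 600) {
  data_norm <- normalize_image(render_projection_image(tensor, src_system))
  obj <- function(par) {
    anchors <- matrix(par[1:6], 3, 2)
    if (abs(signed_area2(anchors)) < 1e-6) return(1e6)
    mp <- topo_mapping(src_system, bary_system(anchors),
                       kernel_width = exp(par[7]))
    ideal <- synth_projection_tensor(atlas, flatmap, mp,
                                     tensor$source_region,
                                     tensor$target_region, 1, 0,
                                     check_anchors = FALSE)
    mn <- suppressWarnings(
      normalize_image(render_projection_image(ideal, src_system)))
    if (mn$sigma_tgt == 0) return(1e6)  # degenerate: image vanished
    mapping_relative_error(mn$colors, data_norm$colors)
  }
  kw0 <- max(mapping$kernel_width, flatmap$pixel_size / 10)
  par0 <- c(as.numeric(mapping$target$anchors), log(kw0))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  # restart at the optimum: a fresh simplex escapes Nelder-Mead stagnation
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  out <- topo_mapping(src_system, bary_system(matrix(fit$par[1:6], 3, 2)),
                      kernel_width = exp(fit$par[7]),
                      fit_error = fit$value)
  attr(out, "converged") <- fit$convergence == 0
  out
}

#' Fit a full topographic mapping from a projection tensor
#'
#' Convenience wrapper running the whole mapping stage for one projection:
#' pick source anchors in the flattened source region, render and
#' normalize the projection image, fit the target anchors, fit the
#' Gaussian kernel width on a grid, and (optionally but by default)
#' polish anchors and width jointly against the pipeline error.
#'
#' @param tensor a `projection_tensor`.
#' @param atlas,flatmap atlas and flat map.
#' @param lambda,n_restarts,seed passed to [fit_target_anchors()].
#' @param polish run the joint refinement step (default TRUE).
#' @return a fitted `topo_mapping`.
#' @export
fit_topographic_mapping <- function(tensor, atlas, flatmap, lambda = 1,
                                    n_restarts = 8, seed = 0,
                                    polish = TRUE) {
  src_mask <- region_flat_mask(atlas, flatmap, tensor$source_region)
  tgt_mask <- region_flat_mask(atlas, flatmap, tensor$target_region)
  src_sys <- fit_source_anchors(src_mask)
  img <- render_projection_image(tensor, src_sys)
  norm <- normalize_image(img)
  mp <- fit_target_anchors(norm, tgt_mask, src_mask, src_sys,
                           lambda = lambda, n_restarts = n_restarts,
                           seed = seed, pixel_size = flatmap$pixel_size)
  mp$kernel_width <- as.numeric(fit_kernel_width(norm, mp,
                                                 pixel_size = flatmap$pixel_size))
  color_error <- mp$fit_error
  if (polish) {
    mp <- polish_mapping(mp, tensor, atlas, flatmap, src_sys)
  } else {
    mp$fit_error <- mapping_pipeline_error(mp, tensor, atlas, flatmap, src_sys)
  }
  attr(mp, "color_error") <- color_error
  mp
}
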