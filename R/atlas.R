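#' Synthetic voxel atlas with a flat map
#'
#' Builds a small discretized brain volume with two mirror-symmetric
#' hemispheres, rectangular regions tiled along the second (y) axis, cortical
#' layers stacked along the third (depth) axis, and an orthographic flat map
#' that collapses depth. This stands in for a full anatomical atlas and its
#' 2-D surface projection; the downstream pipeline only consumes the lookup
#' interface, so any atlas/flat-map pair with the same fields can be plugged
#' in.
#'
#' Region ids are `1..R` in the left hemisphere and `R+1..2R` in the right,
#' where region `r` and `r + R` are mirror homologues. Region volumes are
#' exact voxel counts times `voxel_size^3`. Each region is assigned to a
#' module (round-robin over `n_modules`) and given a hierarchy score (its
#' within-hemisphere index), mirrored across hemispheres.
#'
#' @param n_regions regions per hemisphere (>= 2).
#' @param n_layers number of layers (>= 2).
#' @param dims integer vector `c(nx, ny, nz)` of grid extents; `nx` must be
#'   even (hemisphere split), `ny` divisible into nonempty region bands.
#' @param voxel_size voxel edge length in micrometers.
#' @param n_modules number of region modules.
#' @param region_rows optional integer vector of y-extents (voxels) per
#'   region; must sum to `ny`. A zero extent is an error.
#' @param seed integer seed (layout is deterministic; kept for API symmetry).
#' @return A list with components `atlas` (class `voxel_atlas`) and
#'   `flatmap` (class `flat_map`).
#' @export
build_synthetic_atlas <- function(n_regions = 2, n_layers = 6,
                                  dims = c(10, 10, 12), voxel_size = 100,
                                  n_modules = 2, region_rows = NULL,
                                  seed = 0) {
  stopifnot(n_regions >= 2, n_layers >= 2, length(dims) == 3, all(dims >= 1))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  if (nx %% 2 != 0) stop("first extent must be even (two hemispheres)")
  if (nz < n_layers) stop("depth extent smaller than number of layers")
  if (is.null(region_rows)) {
    base <- ny %/% n_regions
    region_rows <- rep(base, n_regions)
    extra <- ny - base * n_regions
    if (extra > 0) region_rows[seq_len(extra)] <- region_rows[seq_len(extra)] + 1L
  }
  if (length(region_rows) != n_regions || sum(region_rows) != ny) {
    stop("region_rows must have one entry per region and sum to ny")
  }
  if (any(region_rows <= 0)) stop("zero-extent region in atlas specification")

  labels <- array(0L, dim = dims)
  layer_labels <- array(0L, dim = dims)
  hemisphere <- array(0L, dim = dims)

  y_hi <- cumsum(region_rows)
  y_lo <- c(1L, head(y_hi, -1L) + 1L)
  half <- nx %/% 2
  # layers: split depth into n_layers contiguous bands, layer 1 on top
  layer_of_z <- rep(seq_len(n_layers), length.out = nz,
                    each = ceiling(nz / n_layers))[seq_len(nz)]
  for (r in seq_len(n_regions)) {
    ys <- y_lo[r]:y_hi[r]
    labels[1:half, ys, ] <- r
    labels[(half + 1):nx, ys, ] <- r + n_regions
  }
  hemisphere[1:half, , ] <- 1L
  hemisphere[(half + 1):nx, , ] <- 2L
  for (k in seq_len(nz)) layer_labels[, , k] <- layer_of_z[k]

  region_ids <- seq_len(2L * n_regions)
  counts <- tabulate(labels[labels > 0L], nbins = 2L * n_regions)
  region_volumes <- counts * voxel_size^3
  names(region_volumes) <- as.character(region_ids)
  modules <- ((seq_len(n_regions) - 1L) %% n_modules) + 1L
  modules <- c(modules, modules)
  names(modules) <- as.character(region_ids)
  hierarchy <- c(seq_len(n_regions), seq_len(n_regions))
  names(hierarchy) <- as.character(region_ids)

  atlas <- structure(list(
    labels = labels, layer_labels = layer_labels, hemisphere = hemisphere,
    voxel_size = voxel_size, region_volumes = region_volumes,
    modules = modules, hierarchy_score = hierarchy,
    n_regions_per_hemisphere = n_regions, n_layers = n_layers,
    layer_of_z = layer_of_z
  ), class = "voxel_atlas")
  flatmap <- structure(list(
    pixel_size = voxel_size, nx = nx, ny = ny
  ), class = "flat_map")
  list(atlas = atlas, flatmap = flatmap)
}

#' @export
print.voxel_atlas <- function(x, ...) {
  cat("Synthetic voxel atlas:", paste(dim(x$labels), collapse = " x "),
      "voxels at", x$voxel_size, "um\n")
  cat(" ", length(x$region_volumes), "regions (",
      x$n_regions_per_hemisphere, "per hemisphere ),", x$n_layers, "layers\n")
  invisible(x)
}

#' Mirror homologue of a region
#' @param atlas a `voxel_atlas`.
#' @param region region id.
#' @return the id of the region's contralateral homologue.
#' @export
mirror_region <- function(atlas, region) {
  R <- atlas$n_regions_per_hemisphere
  if (!region %in% seq_len(2 * R)) stop("region without a mirror partner: ", region)
  ifelse(region > R, region - R, region + R)
}

#' Flat-map position of voxel indices
#'
#' The flat map is the orthographic projection collapsing the depth axis:
#' a voxel `(i, j, k)` maps to the micrometre coordinates of the center of
#' pixel `(i, j)`.
#' @param flatmap a `flat_map`.
#' @param i,j voxel/pixel indices (1-based, vectorized).
#' @return a matrix with columns `x`, `y` in micrometers.
#' @export
flat_position <- function(flatmap, i, j) {
  cbind(x = (i - 0.5) * flatmap$pixel_size, y = (j - 0.5) * flatmap$pixel_size)
}

#' Voxels of a region
#' @param atlas a `voxel_atlas`.
#' @param region region id.
#' @return data.frame of voxel indices `i, j, k` plus `layer`.
#' @export
region_voxels <- function(atlas, region) {
  idx <- which(atlas$labels == region, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
             layer = atlas$layer_labels[idx])
}

#' Flat-space pixel mask of a region
#' @param atlas a `voxel_atlas`.
#' @param flatmap the matching `flat_map`.
#' @param region region id.
#' @return data.frame of pixel indices `i, j` and center coordinates `x, y`.
#' @export
region_flat_mask <- function(atlas, flatmap, region) {
  v <- unique(region_voxels(atlas, region)[, c("i", "j")])
  pos <- flat_position(flatmap, v$i, v$j)
  out <- data.frame(i = v$i, j = v$j, x = pos[, "x"], y = pos[, "y"])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Per-layer thicknesses of the synthetic atlas
#' @param atlas a `voxel_atlas`.
#' @return named numeric vector of layer thicknesses in micrometers.
#' @export
layer_thicknesses <- function(atlas) {
  tab <- tabulate(atlas$layer_of_z, nbins = atlas$n_layers)
  out <- tab * atlas$voxel_size
  names(out) <- as.character(seq_len(atlas$n_layers))
  out
}
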