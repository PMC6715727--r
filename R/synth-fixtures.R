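#' Synthetic voxelized projection tensor with planted topography
#'
#' Emulates a voxel-level projection model for one source/target region pair:
#' the expected strength from a source voxel `v` to a target pixel `q` is
#' `base_strength * exp(-|q - map(v)|^2 / (2 w^2))` where `map` is a planted
#' topographic mapping and `w` its Gaussian kernel width, plus seeded
#' non-negative half-normal noise. The planted mapping is stored on the
#' result so downstream fitting can be checked against ground truth.
#'
#' With `kernel_width = 0` each source voxel projects only to the pixel
#' nearest its mapped point.
#'
#' @param atlas,flatmap a synthetic atlas and its flat map.
#' @param mapping a `topo_mapping` with anchors inside the two regions.
#' @param source_region,target_region region ids.
#' @param base_strength non-negative scalar strength for the pair.
#' @param noise_sd standard deviation of the half-normal noise (>= 0).
#' @param seed integer seed.
#' @param class_label projection class label stored on the tensor.
#' @param check_anchors verify mapping anchors lie inside their region
#'   masks (default TRUE).
#' @return an object of class `projection_tensor` with fields
#'   `source_voxels`, `target_pixels`, `strengths` (voxels x pixels),
#'   `ground_truth`.
#' @export
synth_projection_tensor <- function(atlas, flatmap, mapping,
                                    source_region, target_region,
                                    base_strength = 1, noise_sd = 0,
                                    seed = 0, class_label = "wild_type",
                                    check_anchors = TRUE) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(base_strength >= 0)
  src_vox <- region_voxels(atlas, source_region)
  tgt_mask <- region_flat_mask(atlas, flatmap, target_region)
  src_mask <- region_flat_mask(atlas, flatmap, source_region)
  if (check_anchors) {
    check_anchor_inside(mapping$source, src_mask, flatmap$pixel_size)
    check_anchor_inside(mapping$target, tgt_mask, flatmap$pixel_size)
  }

  src_flat <- flat_position(flatmap, src_vox$i, src_vox$j)
  mapped <- map_source_to_target(src_flat, mapping)$point
  qx <- tgt_mask$x; qy <- tgt_mask$y
  d2 <- outer(mapped[, 1], qx, "-")^2 + outer(mapped[, 2], qy, "-")^2
  w <- mapping$kernel_width
  if (base_strength == 0) {
    strengths <- matrix(0, nrow(src_vox), nrow(tgt_mask))
  } else if (w <= 0) {
    strengths <- matrix(0, nrow(src_vox), nrow(tgt_mask))
    nearest <- max.col(-d2, ties.method = "first")
    strengths[cbind(seq_len(nrow(src_vox)), nearest)] <- base_strength
  } else {
    strengths <- base_strength * exp(-d2 / (2 * w^2))
  }
  if (noise_sd > 0) {
    strengths <- strengths + local_seed(seed, {
      abs(matrix(stats::rnorm(length(strengths), 0, noise_sd),
                 nrow(strengths), ncol(strengths)))
    })
  }
  structure(list(
    source_region = source_region, target_region = target_region,
    class_label = class_label,
    source_voxels = cbind(src_vox, src_flat),
    target_pixels = tgt_mask,
    strengths = strengths,
    ground_truth = mapping
  ), class = "projection_tensor")
}

check_anchor_inside <- function(sys, mask, pixel_size) {
  for (r in 1:3) {
    d <- sqrt((mask$x - sys$anchors[r, 1])^2 + (mask$y - sys$anchors[r, 2])^2)
    if (min(d) > pixel_size) {
      stop("planted mapping anchor lies outside its region mask")
    }
  }
  invisible(TRUE)
}

#' Synthetic projection tensors for all region pairs with nonzero strength
#'
#' @param atlas,flatmap atlas and flat map.
#' @param mappings named list of `topo_mapping`, keyed `"src->tgt"`.
#' @param base_strengths region x region matrix (dimnames = region ids).
#' @param noise_sd,seed see [synth_projection_tensor()].
#' @return named list of `projection_tensor` objects.
#' @export
synth_projection_tensors <- function(atlas, flatmap, mappings, base_strengths,
                                     noise_sd = 0, seed = 0) {
  out <- list()
  for (key in names(mappings)) {
    st <- strsplit(key, "->", fixed = TRUE)[[1]]
    src <- as.integer(st[1]); tgt <- as.integer(st[2])
    b <- base_strengths[as.character(src), as.character(tgt)]
    if (b <= 0) next
    out[[key]] <- synth_projection_tensor(
      atlas, flatmap, mappings[[key]], src, tgt, base_strength = b,
      noise_sd = noise_sd, seed = derive_seed(seed, key))
  }
  out
}

#' Synthetic neuron and dendritic-segment tables
#'
#' Places neurons in the atlas with per-layer Poisson counts (expected
#' `neurons_per_voxel[layer]` per voxel) and uniform positions within their
#' voxel, assigns morphological types, and gives each neuron at least one
#' dendritic segment. Segment voxels are drawn uniformly over the neuron's
#' region (dendrites span layers); flat positions are looked up at the
#' segment midpoint's voxel.
#'
#' Default morphological types: 15% interneurons (`INT`); layer-5 pyramidal
#' cells split thick-tufted / slender-tufted / untufted (`L5_TPC`,
#' `L5_STPC`, `L5_UPC`) 50/30/20; other layers generic pyramidal (`PC`).
#'
#' @param atlas,flatmap atlas and flat map.
#' @param neurons_per_voxel numeric vector, one expected count per layer
#'   (recycled to `n_layers`). Must be >= 0.
#' @param segments_per_neuron expected segments per neuron (>= 1).
#' @param interneuron_fraction fraction of neurons typed `INT`.
#' @param seed integer seed.
#' @return list with data.frames `neurons` (id, region, layer, mtype, x, y,
#'   z, flat_x, flat_y) and `segments` (id, neuron_id, region, layer, x, y,
#'   z, flat_x, flat_y, length).
#' @export
synth_neurons_and_segments <- function(atlas, flatmap,
                                       neurons_per_voxel = 1,
                                       segments_per_neuron = 4,
                                       interneuron_fraction = 0.15,
                                       seed = 0) {
  lam <- rep(neurons_per_voxel, length.out = atlas$n_layers)
  if (any(lam < 0)) stop("neuron densities must be non-negative")
  stopifnot(segments_per_neuron >= 1)
  vs <- atlas$voxel_size
  local_seed(seed, {
    idx <- which(atlas$labels > 0L, arr.ind = TRUE)
    layer <- atlas$layer_labels[idx]
    counts <- stats::rpois(nrow(idx), lam[layer])
    keep <- counts > 0
    if (!any(keep)) {
      neurons <- data.frame(id = integer(), region = integer(),
                            layer = integer(), mtype = character(),
                            x = numeric(), y = numeric(), z = numeric(),
                            flat_x = numeric(), flat_y = numeric())
      segments <- data.frame(id = integer(), neuron_id = integer(),
                             region = integer(), layer = integer(),
                             x = numeric(), y = numeric(), z = numeric(),
                             flat_x = numeric(), flat_y = numeric(),
                             length = numeric())
      return(list(neurons = neurons, segments = segments))
    }
    vox <- idx[rep(which(keep), counts[keep]), , drop = FALSE]
    n <- nrow(vox)
    lay <- atlas$layer_labels[vox]
    reg <- atlas$labels[vox]
    pos <- (vox - matrix(stats::runif(3 * n), n, 3)) * vs
    flat <- flat_position(flatmap, vox[, 1], vox[, 2])
    mtype <- ifelse(stats::runif(n) < interneuron_fraction, "INT",
                    ifelse(lay == 5,
                           sample(c("L5_TPC", "L5_STPC", "L5_UPC"), n,
                                  replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                           "PC"))
    ord <- order(reg, lay)
    neurons <- data.frame(id = seq_len(n), region = reg[ord],
                          layer = lay[ord], mtype = mtype[ord],
                          x = pos[ord, 1], y = pos[ord, 2], z = pos[ord, 3],
                          flat_x = flat[ord, "x"], flat_y = flat[ord, "y"])

    nseg <- 1L + stats::rpois(n, segments_per_neuron - 1)
    seg_neuron <- rep(neurons$id, nseg)
    seg_region <- rep(neurons$region, nseg)
    m <- length(seg_neuron)
    # uniform voxel of the neuron's region per segment
    reg_vox <- lapply(seq_along(atlas$region_volumes), function(r) {
      which(atlas$labels == r, arr.ind = TRUE)
    })
    seg_vox <- matrix(0L, m, 3)
    for (r in unique(seg_region)) {
      rows <- which(seg_region == r)
      rv <- reg_vox[[r]]
      seg_vox[rows, ] <- rv[sample.int(nrow(rv), length(rows), replace = TRUE), ]
    }
    seg_pos <- (seg_vox - matrix(stats::runif(3 * m), m, 3)) * vs
    seg_flat <- flat_position(flatmap, seg_vox[, 1], seg_vox[, 2])
    segments <- data.frame(id = seq_len(m), neuron_id = seg_neuron,
                           region = seg_region,
                           layer = atlas$layer_labels[seg_vox],
                           x = seg_pos[, 1], y = seg_pos[, 2],
                           z = seg_pos[, 3],
                           flat_x = seg_flat[, "x"], flat_y = seg_flat[, "y"],
                           length = stats::runif(m, 2, 10))
    list(neurons = neurons, segments = segments)
  })
}

#' Synthetic single-axon innervation table
#'
#' Samples binary axon-by-region innervation profiles from a projection-type
#' tree, standing in for reconstructed-axon tables. Delegates to
#' [sample_innervation_profiles()].
#'
#' @param tree a `ptype_tree`.
#' @param source_region a leaf region id/name of `tree`.
#' @param n_axons number of axons (rows).
#' @param seed integer seed.
#' @return binary matrix `n_axons x n_leaves` (source column all zero).
#' @export
synth_axon_table <- function(tree, source_region, n_axons, seed = 0) {
  sample_innervation_profiles(tree, source_region, n_axons, seed)
}

#' Write / read neuron and segment tables as TSV
#' @param tables list with `neurons` and `segments` data.frames.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cell_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pn <- file.path(dir, "neurons.tsv")
  ps <- file.path(dir, "segments.tsv")
  utils::write.table(tables$neurons, pn, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(tables$segments, ps, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(neurons = pn, segments = ps))
}

#' @rdname write_cell_tables
#' @export
read_cell_tables <- function(dir) {
  list(
    neurons = utils::read.table(file.path(dir, "neurons.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE),
    segments = utils::read.table(file.path(dir, "segments.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  )
}
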