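#' Allocate source neurons to projections
#'
#' Greedy allocation: each projection receives a random sample of
#' `round(fraction * N)` neurons; then, for every pair with a specified
#' interaction, the required overlap `round(f_a * f_b * increase * N)` is
#' enforced by sampling neurons from one group and swapping them in for
#' members of the other. Pairs without a specified interaction default to
#' the independence product.
#'
#' @param population vector of neuron ids.
#' @param fractions named vector of participation fractions in `[0, 1]`,
#'   one per projection.
#' @param interactions optional data.frame with columns `a`, `b`
#'   (projection names) and `increase` (conditional increase, >= 1).
#' @param seed integer seed.
#' @return named list: projection -> vector of neuron ids.
#' @export
allocate_source_neurons <- function(population, fractions,
                                    interactions = NULL, seed = 0) {
  N <- length(population)
  if (N == 0) stop("empty population")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
  local_seed(seed, {
    sets <- lapply(fractions, function(f) {
      sample(population, round(f * N))
    })
    names(sets) <- names(fractions)
    if (!is.null(interactions) && nrow(interactions)) {
      for (r in seq_len(nrow(interactions))) {
        a <- as.character(interactions$a[r])
        b <- as.character(interactions$b[r])
        inc <- interactions$increase[r]
        if (inc < 1) stop("conditional increases must be >= 1")
        required <- round(fractions[[a]] * fractions[[b]] * inc * N)
        if (required > min(length(sets[[a]]), length(sets[[b]]))) {
          stop(sprintf("infeasible overlap for pair (%s, %s): need %d > %d",
                       a, b, required,
                       min(length(sets[[a]]), length(sets[[b]]))))
        }
        overlap <- sum(sets[[a]] %in% sets[[b]])
        d <- required - overlap
        if (d > 0) {
          only_a <- setdiff(sets[[a]], sets[[b]])
          only_b <- setdiff(sets[[b]], sets[[a]])
          add <- sample(only_a, d)
          drop <- sample(only_b, d)
          sets[[b]] <- c(setdiff(sets[[b]], drop), add)
        }
      }
    }
    sets
  })
}

#' Expected and realized synapse counts per target voxel
#'
#' Translates a projection's synapse density into per-voxel counts over
#' the targeted subvolume: the expected total is density times targeted
#' volume; it is distributed over layers proportionally to (layer profile
#' value x layer thickness) and uniformly over the voxels within a layer.
#' Fractional expectations are realized by stochastic rounding, which
#' preserves the expectation exactly.
#'
#' @param density synapse density in um^-3 (>= 0).
#' @param atlas a `voxel_atlas`.
#' @param target_region target region id.
#' @param layer_profile relative density per layer (recycled to
#'   `n_layers`); default flat.
#' @param voxels optional data.frame (`i`, `j`, `k`, `layer`) restricting
#'   the targeted subvolume; default the whole region.
#' @param seed integer seed.
#' @return the voxel data.frame with columns `expected` and `count`;
#'   attribute `expected_total`.
#' @export
projection_synapse_counts <- function(density, atlas, target_region,
                                      layer_profile = 1, voxels = NULL,
                                      seed = 0) {
  if (density < 0) stop("density must be >= 0")
  if (is.null(voxels)) voxels <- region_voxels(atlas, target_region)
  if (nrow(voxels) == 0) {
    warning("empty target subvolume; zero synapse counts")
    voxels$expected <- numeric(0)
    voxels$count <- integer(0)
    attr(voxels, "expected_total") <- 0
    return(voxels)
  }
  prof <- rep(layer_profile, length.out = atlas$n_layers)
  th <- layer_thicknesses(atlas)
  total <- density * nrow(voxels) * atlas$voxel_size^3
  lw <- prof * th                      # layer weight: profile x thickness
  nvox_layer <- tabulate(voxels$layer, nbins = atlas$n_layers)
  lw[nvox_layer == 0] <- 0
  if (sum(lw) == 0) {
    voxels$expected <- rep(0, nrow(voxels))
  } else {
    per_layer <- total * lw / sum(lw)
    voxels$expected <- per_layer[voxels$layer] / nvox_layer[voxels$layer]
  }
  voxels$count <- local_seed(seed, {
    fl <- floor(voxels$expected)
    as.integer(fl + (stats::runif(nrow(voxels)) < voxels$expected - fl))
  })
  attr(voxels, "expected_total") <- total
  voxels
}

#' Place synapses on dendritic segments
#'
#' Within each target voxel, the required number of synapses is drawn from
#' the segments lying in that voxel, sampled with replacement with weights
#' proportional to segment length; each synapse gets a uniform offset
#' along its segment. Voxels containing no segments hand their counts to
#' the nearest voxel that has some (logged in the `reassigned` attribute).
#'
#' @param counts voxel data.frame from [projection_synapse_counts()].
#' @param segments segment table (see [synth_neurons_and_segments()]),
#'   already filtered to the target population.
#' @param atlas a `voxel_atlas`.
#' @param seed integer seed.
#' @return data.frame of placed synapses: `segment_id`, `target_neuron`,
#'   `region`, `layer`, `x`, `y`, `z`, `flat_x`, `flat_y`, `offset`.
#' @export
sample_synapse_positions <- function(counts, segments, atlas, seed = 0) {
  counts <- counts[counts$count > 0, , drop = FALSE]
  empty <- data.frame(segment_id = integer(), target_neuron = integer(),
                      region = integer(), layer = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      flat_x = numeric(), flat_y = numeric(),
                      offset = numeric())
  if (nrow(counts) == 0) return(empty)
  if (nrow(segments) == 0) stop("no segments available in the target")
  vs <- atlas$voxel_size
  seg_vox <- cbind(ceiling(segments$x / vs), ceiling(segments$y / vs),
                   ceiling(segments$z / vs))
  seg_key <- paste(seg_vox[, 1], seg_vox[, 2], seg_vox[, 3])
  seg_by_vox <- split(seq_len(nrow(segments)), seg_key)
  occupied <- do.call(rbind, lapply(strsplit(names(seg_by_vox), " "),
                                    as.integer))
  reassigned <- 0L
  local_seed(seed, {
    rows <- vector("list", nrow(counts))
    for (r in seq_len(nrow(counts))) {
      key <- paste(counts$i[r], counts$j[r], counts$k[r])
      segs <- seg_by_vox[[key]]
      if (is.null(segs)) {
        d2 <- (occupied[, 1] - counts$i[r])^2 +
          (occupied[, 2] - counts$j[r])^2 +
          (occupied[, 3] - counts$k[r])^2
        segs <- seg_by_vox[[which.min(d2)]]
        reassigned <- reassigned + counts$count[r]
      }
      pick <- segs[sample.int(length(segs), counts$count[r], replace = TRUE,
                              prob = segments$length[segs])]
      rows[[r]] <- data.frame(
        segment_id = segments$id[pick],
        target_neuron = segments$neuron_id[pick],
        region = segments$region[pick],
        layer = segments$layer[pick],
        x = segments$x[pick], y = segments$y[pick], z = segments$z[pick],
        flat_x = segments$flat_x[pick], flat_y = segments$flat_y[pick],
        offset = stats::runif(length(pick)))
    }
    out <- do.call(rbind, rows)
    attr(out, "reassigned") <- reassigned
    out
  })
}

#' Assign presynaptic neurons to placed synapses
#'
#' Each allocated source neuron's flat position is mapped through the
#' projection's topographic mapping into the target flat space. For each
#' synapse the `k` nearest mapped source positions (all of them, if
#' fewer) are candidates; one is drawn with probability proportional to
#' an isotropic Gaussian of the mapping's kernel width evaluated at the
#' synapse-candidate distance. A kernel width of 0 means a uniform draw
#' over the tied nearest candidates. The nearest-`k` query is exact, with
#' ties at the k-th distance broken by neuron id.
#'
#' @param synapses placed synapses from [sample_synapse_positions()].
#' @param source_ids allocated source neuron ids for this projection.
#' @param neurons the neuron table (for flat positions).
#' @param mapping the projection's `topo_mapping` (source region to
#'   target region).
#' @param k number of nearest candidates (default 100).
#' @param seed integer seed.
#' @return object of class `synapse_table`: the synapse data.frame with a
#'   `source_neuron` column.
#' @export
assign_presynaptic_neurons <- function(synapses, source_ids, neurons,
                                       mapping, k = 100, seed = 0) {
  if (length(source_ids) == 0) stop("empty allocated source set")
  src <- neurons[match(source_ids, neurons$id), , drop = FALSE]
  ord <- order(src$id)
  src <- src[ord, , drop = FALSE]
  mapped <- map_source_to_target(as.matrix(src[, c("flat_x", "flat_y")]),
                                 mapping)$point
  sigma <- mapping$kernel_width
  n <- nrow(synapses)
  out <- synapses
  out$source_neuron <- NA_integer_
  if (n == 0) return(structure(out, class = c("synapse_table", "data.frame")))
  local_seed(seed, {
    kk <- min(k, nrow(src))
    for (s in seq_len(n)) {
      d2 <- (mapped[, 1] - synapses$flat_x[s])^2 +
        (mapped[, 2] - synapses$flat_y[s])^2
      # exact k nearest; order() on (distance, id) breaks ties by neuron id
      nearest <- order(d2, src$id)[seq_len(kk)]
      if (sigma <= 0) {
        dmin <- min(d2[nearest])
        cand <- nearest[d2[nearest] <= dmin + 1e-12]
        pick <- cand[sample.int(length(cand), 1)]
      } else {
        w <- exp(-(d2[nearest] - min(d2[nearest])) / (2 * sigma^2))
        pick <- nearest[sample.int(kk, 1, prob = w)]
      }
      out$source_neuron[s] <- src$id[pick]
    }
    structure(out, class = c("synapse_table", "data.frame"))
  })
}

#' @export
print.synapse_table <- function(x, ...) {
  cat("Synapse table:", nrow(x), "synapses,",
      length(unique(x$source_neuron)), "source neurons,",
      length(unique(x$target_neuron)), "target neurons\n")
  invisible(x)
}

#' Projection-class membership of neurons
#'
#' Pyramidal neurons in layers 2/3, 4 and 6 join their layer's projection
#' class; slender-tufted and untufted layer-5 cells join L5IT; each
#' thick-tufted layer-5 cell joins L5PT with probability one half (the
#' rest are corticothalamic and outside this purely cortical model).
#' Interneurons get no class. Unknown types get no class, with a warning.
#'
#' @param neurons neuron table with `mtype` and `layer`.
#' @param seed integer seed (for the thick-tufted coin flip).
#' @return character vector of classes (`NA` = not participating).
#' @export
assign_projection_classes <- function(neurons, seed = 0) {
  known <- c("PC", "INT", "L5_TPC", "L5_STPC", "L5_UPC")
  if (any(!neurons$mtype %in% known)) {
    warning("unknown morphological types assigned no projection class: ",
            paste(unique(setdiff(neurons$mtype, known)), collapse = ", "))
  }
  local_seed(seed, {
    cls <- rep(NA_character_, nrow(neurons))
    pc <- neurons$mtype == "PC"
    cls[pc & neurons$layer %in% c(2, 3)] <- "L2/3"
    cls[pc & neurons$layer == 4] <- "L4"
    cls[pc & neurons$layer == 6] <- "L6"
    cls[neurons$mtype %in% c("L5_STPC", "L5_UPC")] <- "L5IT"
    tpc <- which(neurons$mtype == "L5_TPC")
    heads <- stats::runif(length(tpc)) < 0.5
    cls[tpc[heads]] <- "L5PT"
    cls
  })
}
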