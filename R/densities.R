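#' Total synapse budget from mean density and cortical volume
#'
#' Multiplies a mean volumetric synapse density (per cubic micrometer) by a
#' cortical volume (cubic millimeters), converting units
#' (1 mm^3 = 1e9 um^3). With the measured neocortical mean density of
#' 0.72 um^-3 and an isocortex volume of 123.2 mm^3 this gives the target
#' of about 88.74 billion synapses.
#'
#' @param mean_density mean synapse density in um^-3 (>= 0).
#' @param cortex_volume cortical volume in mm^3 (>= 0).
#' @return total synapse count.
#' @export
total_synapse_budget <- function(mean_density = 0.72, cortex_volume = 123.2) {
  if (mean_density < 0 || cortex_volume < 0) {
    stop("density and volume must be non-negative")
  }
  mean_density * cortex_volume * 1e9
}

#' Construct a projection-strength matrix pair
#'
#' Bundles ipsilateral and contralateral region-by-region strength matrices.
#' The main diagonal of the ipsilateral matrix (within-region connectivity,
#' which is local and handled outside the long-range model) is forced to 0.
#'
#' @param ipsi,contra square non-negative matrices with identical region
#'   dimnames.
#' @param units `"raw"` (tracer strength) or `"um^-3"` (synapse density).
#' @return object of class `projection_matrix`.
#' @export
projection_matrix <- function(ipsi, contra = NULL, units = "raw") {
  ipsi <- as.matrix(ipsi)
  if (is.null(contra)) contra <- array(0, dim(ipsi), dimnames = dimnames(ipsi))
  contra <- as.matrix(contra)
  stopifnot(nrow(ipsi) == ncol(ipsi), all(dim(ipsi) == dim(contra)))
  if (any(ipsi < 0) || any(contra < 0)) stop("projection strengths must be >= 0")
  diag(ipsi) <- 0
  structure(list(ipsi = ipsi, contra = contra, units = units),
            class = "projection_matrix")
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("Projection matrix pair (", x$units, "), ", nrow(x$ipsi),
      " regions; total ipsi ", signif(sum(x$ipsi), 4), ", contra ",
      signif(sum(x$contra), 4), "\n", sep = "")
  invisible(x)
}

#' Scaling factor from raw strengths to synapse densities
#'
#' Finds the factor `sigma` such that
#' `sigma * sum_ab (M_i + M_c)[a,b] * V[b] * C_t[a,b]` equals the long-range
#' synapse budget, and applies it to both matrices, converting them into
#' volumetric synapse densities (um^-3) averaged over the full cortical
#' depth of the target region.
#'
#' @param wt a `projection_matrix` in raw units.
#' @param V named vector of region volumes (um^3), one per region.
#' @param C_t region x region target-coverage fractions in `[0, 1]`
#'   (default all ones).
#' @param long_range_budget total long-range synapse count to distribute
#'   (default 68.74e9).
#' @return list with `sigma` and `scaled` (a `projection_matrix` in um^-3).
#' @export
compute_scaling_factor <- function(wt, V, C_t = NULL,
                                   long_range_budget = 68.74e9) {
  stopifnot(inherits(wt, "projection_matrix"))
  n <- nrow(wt$ipsi)
  if (is.null(C_t)) C_t <- array(1, c(n, n), dimnames = dimnames(wt$ipsi))
  if (any(C_t < 0 | C_t > 1)) stop("coverage fractions must lie in [0, 1]")
  if (any(V <= 0)) stop("region volumes must be positive")
  V <- V[colnames(wt$ipsi)]
  denom <- sum((wt$ipsi + wt$contra) *
                 matrix(V, n, n, byrow = TRUE) * C_t)
  if (denom <= 0) stop("zero total projection strength; cannot scale")
  sigma <- long_range_budget / denom
  scaled <- projection_matrix(sigma * wt$ipsi, sigma * wt$contra,
                              units = "um^-3")
  list(sigma = sigma, scaled = scaled)
}

#' Split a wild-type density matrix into per-class matrices
#'
#' The five projection classes (L2/3, L4, L5IT, L5PT, L6) are modeled as
#' versions of the wild-type matrix where module-to-module submatrices are
#' scaled by class-specific weights. Weights are normalized per
#' (source module, target module) cell so the five class matrices sum to
#' the wild-type exactly. Source regions lacking layer 4 get a zero L4 row.
#'
#' @param wt_scaled a `projection_matrix` in um^-3.
#' @param class_module_weights named list, one module x module non-negative
#'   matrix per class.
#' @param modules named vector region id -> module id.
#' @param regions_without_l4 region ids whose L4 class rows are zeroed.
#' @return object of class `class_split`: list of per-class
#'   `projection_matrix` plus the normalized weights.
#' @export
split_by_class <- function(wt_scaled, class_module_weights, modules,
                           regions_without_l4 = integer()) {
  stopifnot(inherits(wt_scaled, "projection_matrix"))
  classes <- names(class_module_weights)
  if (is.null(classes)) stop("class_module_weights must be a named list")
  mods <- sort(unique(modules))
  W <- lapply(class_module_weights, as.matrix)
  if (any(vapply(W, function(w) any(w < 0), logical(1)))) {
    stop("class module weights must be >= 0")
  }
  tot <- Reduce("+", W)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("all-zero class weights for module cell (%s, %s)",
                 rownames(tot)[bad[1]] %||% bad[1],
                 colnames(tot)[bad[2]] %||% bad[2]))
  }
  Wn <- lapply(W, function(w) w / tot)

  regs <- rownames(wt_scaled$ipsi)
  msrc <- modules[regs]
  mi <- match(msrc, mods)
  # region-level weights; zero the L4 rows of regions lacking layer 4 and
  # renormalize the remaining classes so the split still sums to the wild type
  Wr <- lapply(Wn, function(wm) wm[mi, mi, drop = FALSE])
  if ("L4" %in% classes && length(regions_without_l4)) {
    rows <- regs %in% as.character(regions_without_l4)
    Wr$L4[rows, ] <- 0
    tot_r <- Reduce("+", Wr)
    if (any(tot_r <= 0)) {
      stop("a module cell has only L4 weight but its source lacks layer 4")
    }
    Wr <- lapply(Wr, function(w) w / tot_r)
  }
  # one (non-L4) class absorbs the residual: conservation exact by construction
  residual <- rev(c(classes[classes != "L4"], classes))[1]
  out <- list()
  acc_i <- 0 * wt_scaled$ipsi
  acc_c <- 0 * wt_scaled$contra
  for (cl in setdiff(classes, residual)) {
    ipsi <- wt_scaled$ipsi * Wr[[cl]]
    contra <- wt_scaled$contra * Wr[[cl]]
    acc_i <- acc_i + ipsi
    acc_c <- acc_c + contra
    dimnames(ipsi) <- dimnames(contra) <- dimnames(wt_scaled$ipsi)
    out[[cl]] <- projection_matrix(ipsi, contra, units = "um^-3")
  }
  ipsi <- wt_scaled$ipsi - acc_i
  contra <- wt_scaled$contra - acc_c
  ipsi[ipsi < 0] <- 0
  contra[contra < 0] <- 0
  dimnames(ipsi) <- dimnames(contra) <- dimnames(wt_scaled$ipsi)
  out[[residual]] <- projection_matrix(ipsi, contra, units = "um^-3")
  out <- out[classes]
  structure(list(classes = out, weights = Wn, modules = modules,
                 wild_type = wt_scaled,
                 regions_without_l4 = regions_without_l4),
            class = "class_split")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.class_split <- function(x, ...) {
  cat("Class split over", length(x$classes), "projection classes:",
      paste(names(x$classes), collapse = ", "), "\n")
  tot <- sum(vapply(x$classes, function(m) sum(m$ipsi) + sum(m$contra),
                    numeric(1)))
  cat("  total density mass", signif(tot, 6), "um^-3\n")
  invisible(x)
}

#' Enumerate projections of a class split
#'
#' @param split a `class_split`.
#' @return data.frame with columns class, src, tgt, side
#'   (`ipsi`/`contra`), density.
#' @export
list_projections <- function(split) {
  regs <- rownames(split$classes[[1]]$ipsi)
  out <- list()
  for (cl in names(split$classes)) {
    for (side in c("ipsi", "contra")) {
      m <- split$classes[[cl]][[side]]
      nz <- which(m > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        out[[length(out) + 1L]] <- data.frame(
          class = cl, src = regs[nz[, 1]], tgt = regs[nz[, 2]],
          side = side, density = m[nz], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(class = character(), src = character(),
                      tgt = character(), side = character(),
                      density = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$class, res$side, res$src, res$tgt), , drop = FALSE]
}

#' Minimum-strength cutoff losing less than a bound of synapses
#'
#' Removes the weakest projections: the cutoff is the largest value in the
#' multiset of projection densities such that the synapse count removed
#' (density x target volume x coverage) stays strictly below
#' `max_loss_fraction` of the total. Projections with density strictly
#' below the cutoff are zeroed in every class matrix.
#'
#' @param split a `class_split`.
#' @param V named region volumes (um^3).
#' @param C_t coverage matrix (default all ones).
#' @param max_loss_fraction allowed lost fraction in `[0, 1)`; default 0.05.
#' @return list with `cutoff` (um^-3), `loss_fraction`, `filtered`
#'   (`class_split`), and `removed` (data.frame of dropped projections).
#' @export
apply_strength_cutoff <- function(split, V, C_t = NULL,
                                  max_loss_fraction = 0.05) {
  stopifnot(inherits(split, "class_split"))
  if (max_loss_fraction < 0 || max_loss_fraction >= 1) {
    stop("max_loss_fraction must be in [0, 1)")
  }
  proj <- list_projections(split)
  regs <- rownames(split$classes[[1]]$ipsi)
  n <- length(regs)
  if (is.null(C_t)) C_t <- array(1, c(n, n), dimnames = list(regs, regs))
  V <- V[regs]
  cover <- C_t[cbind(match(proj$src, regs), match(proj$tgt, regs))]
  proj$synapses <- proj$density * V[proj$tgt] * cover
  total <- sum(proj$synapses)
  # cutoff: largest density value such that removing everything strictly
  # below it loses strictly less than the allowed fraction
  cand <- sort(unique(proj$density))
  loss_at <- vapply(cand, function(cc) sum(proj$synapses[proj$density < cc]),
                    numeric(1))
  ok <- loss_at < max_loss_fraction * total
  cutoff <- if (any(ok)) max(cand[ok]) else 0
  removed_idx <- which(proj$density < cutoff)
  loss <- if (total > 0) sum(proj$synapses[removed_idx]) / total else 0
  filtered <- split
  if (length(removed_idx)) {
    rm_df <- proj[removed_idx, , drop = FALSE]
    for (r in seq_len(nrow(rm_df))) {
      cl <- rm_df$class[r]; side <- rm_df$side[r]
      filtered$classes[[cl]][[side]][rm_df$src[r], rm_df$tgt[r]] <- 0
    }
  }
  list(cutoff = cutoff, loss_fraction = loss, filtered = filtered,
       removed = proj[removed_idx, c("class", "src", "tgt", "side",
                                     "density")])
}

#' Mirror projection densities onto both hemispheres
#'
#' The measured ipsi/contra matrices describe sources in one hemisphere.
#' Assuming connectivity symmetric between hemispheres, this expands each
#' class's density pair into one full matrix over all `2R` atlas regions:
#' same-hemisphere entries come from the ipsilateral matrix, cross-
#' hemisphere entries from the contralateral one, so that
#' `D[r -> t] = D[mirror(r) -> mirror(t)]` holds exactly. Within-region
#' (diagonal) entries remain 0 — local connectivity is handled outside the
#' long-range model. The operation is idempotent in the sense that the
#' symmetry predicate holds exactly on the output and re-deriving the full
#' matrix from it changes nothing.
#'
#' @param split a `class_split` over the `R` base (single-hemisphere)
#'   regions.
#' @param atlas the `voxel_atlas` providing the mirror relation (regions
#'   `1..R` and their homologues `R+1..2R`).
#' @return object of class `density_full`: named list `classes` of
#'   `2R x 2R` density matrices plus region bookkeeping.
#' @export
mirror_contralateral <- function(split, atlas) {
  stopifnot(inherits(split, "class_split"))
  R <- atlas$n_regions_per_hemisphere
  regs <- rownames(split$classes[[1]]$ipsi)
  if (length(regs) != R) {
    stop("class split must cover the ", R, " base regions of one hemisphere")
  }
  full_ids <- as.character(seq_len(2L * R))
  base <- match(as.character(c(seq_len(R), seq_len(R))), regs)
  if (anyNA(base)) stop("region without a mirror partner in the matrix")
  hemi <- rep(1:2, each = R)
  same <- outer(hemi, hemi, "==")
  classes <- lapply(split$classes, function(pm) {
    f <- matrix(0, 2L * R, 2L * R, dimnames = list(full_ids, full_ids))
    ip <- pm$ipsi[base, base, drop = FALSE]
    co <- pm$contra[base, base, drop = FALSE]
    f[same] <- ip[same]
    f[!same] <- co[!same]
    diag(f) <- 0
    f
  })
  structure(list(classes = classes, regions = full_ids, atlas_regions = 2L * R),
            class = "density_full")
}

#' Hemispheric-symmetry deviation of a full density matrix set
#' @param full a `density_full`.
#' @param atlas the matching atlas.
#' @return maximum absolute deviation from
#'   `D[r -> t] == D[mirror(r) -> mirror(t)]` over all classes.
#' @export
hemisphere_symmetry_error <- function(full, atlas) {
  R <- atlas$n_regions_per_hemisphere
  midx <- c(R + seq_len(R), seq_len(R))
  max(vapply(full$classes, function(f) {
    max(abs(f - f[midx, midx, drop = FALSE]))
  }, numeric(1)))
}
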