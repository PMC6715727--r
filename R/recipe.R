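#' Build a long-range connectivity recipe from mesoscale constraints
#'
#' Runs the full fitting pipeline — density scaling, class splitting,
#' strength cutoff, hemisphere mirroring, layer-profile assignment,
#' topographic-mapping fits for the supplied projection tensors, and the
#' projection-type tree — and assembles the result into a single recipe
#' describing populations, projections (density, layer profile,
#' barycentric anchor triangles, kernel width) and p-types (first-order
#' innervation fractions and pairwise conditional increases).
#'
#' First-order innervation probabilities are predicted from the
#' normalized projection strength (strength over source volume) with the
#' class constants of [innervation_probability()]; the tree topology
#' comes from the normalized connection density (strength over both
#' volumes).
#'
#' @param atlas,flatmap synthetic or real atlas and flat map.
#' @param wt wild-type `projection_matrix` (raw units) over the base
#'   (single-hemisphere) regions.
#' @param class_module_weights per-class module x module weights
#'   (see [split_by_class()]).
#' @param tables a `frequency_tables`.
#' @param library a `profile_library`.
#' @param tensors named list of `projection_tensor` (key `"src->tgt"`)
#'   for the projections whose mapping should be fitted.
#' @param long_range_budget total long-range synapse budget.
#' @param max_loss_fraction allowed synapse loss at the cutoff.
#' @param C_t target-coverage matrix (default all ones).
#' @param regions_without_l4 regions with no layer 4.
#' @param seed integer root seed.
#' @return object of class `lr_recipe`.
#' @export
build_recipe <- function(atlas, flatmap, wt, class_module_weights,
                         tables, library, tensors = list(),
                         long_range_budget = 68.74e9,
                         max_loss_fraction = 0.05, C_t = NULL,
                         regions_without_l4 = integer(), seed = 0) {
  R <- atlas$n_regions_per_hemisphere
  base_regs <- rownames(wt$ipsi)
  V <- atlas$region_volumes[base_regs]

  sc <- compute_scaling_factor(wt, V, C_t, long_range_budget)
  split <- split_by_class(sc$scaled, class_module_weights,
                          atlas$modules[base_regs], regions_without_l4)
  cut <- apply_strength_cutoff(split, V, C_t, max_loss_fraction)
  full <- mirror_contralateral(cut$filtered, atlas)

  proj <- list_projections_full(full)
  proj <- assign_profiles(proj, tables, library, atlas$modules,
                          atlas$hierarchy_score)

  mappings <- list()
  for (key in names(tensors)) {
    mappings[[key]] <- fit_topographic_mapping(
      tensors[[key]], atlas, flatmap,
      seed = derive_seed(seed, paste0("map-", key)))
  }
  anch_cols <- c("sx1", "sy1", "sx2", "sy2", "sx3", "sy3",
                 "tx1", "ty1", "tx2", "ty2", "tx3", "ty3")
  for (cc in anch_cols) proj[[cc]] <- NA_real_
  proj$kernel_width <- NA_real_
  for (r in seq_len(nrow(proj))) {
    key <- paste0(proj$src[r], "->", proj$tgt[r])
    mp <- mappings[[key]]
    if (!is.null(mp)) {
      proj[r, anch_cols] <- c(t(mp$source$anchors), t(mp$target$anchors))
      proj$kernel_width[r] <- mp$kernel_width
    }
  }

  # p-types: raw-strength expansion to both hemispheres for nps and ncd
  raw_full <- mirror_contralateral(
    structure(list(classes = list(wild_type = wt)), class = "class_split"),
    atlas)$classes$wild_type
  Vfull <- atlas$region_volumes[rownames(raw_full)]
  nps <- raw_full / Vfull[row(raw_full)]
  ncd <- nps / Vfull[col(raw_full)]
  skeleton <- build_tree_topology(ncd, seed = derive_seed(seed, "topology"))
  classes <- names(split$classes)
  trees <- list()
  ptypes <- list()
  for (cl in classes) {
    P <- matrix(innervation_probability(as.numeric(nps), cl),
                nrow(nps), ncol(nps), dimnames = dimnames(nps))
    trees[[cl]] <- fit_edge_probabilities(skeleton, -log10(P))
    prows <- proj[proj$class == cl, , drop = FALSE]
    for (src in unique(prows$src)) {
      tgts <- prows$tgt[prows$src == src]
      fr <- stats::setNames(P[src, tgts], tgts)
      inter <- NULL
      if (length(tgts) >= 2) {
        cmb <- utils::combn(sort(tgts), 2)
        inter <- data.frame(
          a = cmb[1, ], b = cmb[2, ],
          increase = apply(cmb, 2, function(p) {
            conditional_increase(trees[[cl]], src, p[1], p[2])
          }))
      }
      ptypes[[paste0(cl, "|", src)]] <- list(class = cl, source = src,
                                             fractions = fr,
                                             interactions = inter)
    }
  }

  structure(list(
    populations = data.frame(
      region = rep(full$regions, each = length(classes)),
      class = rep(classes, times = length(full$regions)),
      stringsAsFactors = FALSE),
    projections = proj,
    ptypes = ptypes,
    trees = trees,
    mappings = mappings,
    sigma = sc$sigma, cutoff = cut$cutoff,
    loss_fraction = cut$loss_fraction,
    long_range_budget = long_range_budget,
    seed = seed
  ), class = "lr_recipe")
}

#' Enumerate nonzero projections of a full density matrix set
#' @param full a `density_full`.
#' @return data.frame with class, src, tgt, density.
#' @export
list_projections_full <- function(full) {
  out <- list()
  for (cl in names(full$classes)) {
    m <- full$classes[[cl]]
    nz <- which(m > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      out[[length(out) + 1L]] <- data.frame(
        class = cl, src = rownames(m)[nz[, 1]], tgt = colnames(m)[nz[, 2]],
        density = m[nz], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(class = character(), src = character(),
                      tgt = character(), density = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$class, res$src, res$tgt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @export
print.lr_recipe <- function(x, ...) {
  cat("Long-range connectivity recipe\n")
  cat("  ", nrow(x$projections), "projections over",
      length(unique(c(x$projections$src, x$projections$tgt))), "regions;",
      "cutoff", signif(x$cutoff, 4), "um^-3 (loss",
      sprintf("%.2f%%)", 100 * x$loss_fraction), "\n")
  cat("  ", length(x$ptypes), "p-type blocks;",
      length(x$mappings), "fitted mappings\n")
  invisible(x)
}

#' Write / read a recipe as YAML
#'
#' @param recipe an `lr_recipe`.
#' @param path YAML file path.
#' @return `write_recipe` invisibly returns `path`; `read_recipe` returns
#'   the restored `lr_recipe` (fitted tree and mapping objects are
#'   restored from their serialized parameters).
#' @export
write_recipe <- function(recipe, path) {
  proj <- recipe$projections
  doc <- list(
    meta = list(seed = recipe$seed, sigma = recipe$sigma,
                cutoff = recipe$cutoff,
                loss_fraction = recipe$loss_fraction,
                long_range_budget = recipe$long_range_budget),
    populations = lapply(seq_len(nrow(recipe$populations)), function(i) {
      as.list(recipe$populations[i, ])
    }),
    projections = lapply(seq_len(nrow(proj)), function(i) {
      p <- as.list(proj[i, ])
      p$layer_profile <- p$profile
      p$profile <- NULL
      p
    }),
    ptypes = lapply(recipe$ptypes, function(b) {
      list(class = b$class, source = b$source,
           fractions = as.list(b$fractions),
           interactions = if (is.null(b$interactions)) list() else
             lapply(seq_len(nrow(b$interactions)), function(i) {
               as.list(b$interactions[i, ])
             }))
    })
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_recipe
#' @export
read_recipe <- function(path) {
  doc <- yaml::read_yaml(path)
  proj <- do.call(rbind, lapply(doc$projections, function(p) {
    p$profile <- p$layer_profile
    p$layer_profile <- NULL
    as.data.frame(p[!vapply(p, is.null, logical(1))],
                  stringsAsFactors = FALSE)
  }))
  ptypes <- lapply(doc$ptypes, function(b) {
    list(class = b$class, source = b$source,
         fractions = unlist(b$fractions),
         interactions = if (length(b$interactions)) {
           do.call(rbind, lapply(b$interactions, as.data.frame))
         } else NULL)
  })
  structure(list(
    populations = do.call(rbind, lapply(doc$populations, as.data.frame)),
    projections = proj, ptypes = ptypes,
    sigma = doc$meta$sigma, cutoff = doc$meta$cutoff,
    loss_fraction = doc$meta$loss_fraction,
    long_range_budget = doc$meta$long_range_budget,
    seed = doc$meta$seed
  ), class = "lr_recipe")
}

#' Validate a recipe against its atlas
#'
#' Checks the recipe's invariants: densities at or above the cutoff,
#' layer profiles in 1..6, p-type fractions in `[0, 1]`, conditional
#' increases >= 1, and (when anchors are present) anchor triangles
#' non-degenerate. Reports violations; never throws for content
#' problems.
#'
#' @param recipe an `lr_recipe`.
#' @param atlas the matching `voxel_atlas`.
#' @return data.frame of violations (zero rows when valid).
#' @export
validate_recipe <- function(recipe, atlas) {
  v <- list()
  note <- function(where, what) {
    v[[length(v) + 1L]] <<- data.frame(where = where, what = what,
                                       stringsAsFactors = FALSE)
  }
  proj <- recipe$projections
  for (i in seq_len(nrow(proj))) {
    id <- sprintf("projection %s %s->%s", proj$class[i], proj$src[i],
                  proj$tgt[i])
    if (proj$density[i] < recipe$cutoff) {
      note(id, "density below cutoff")
    }
    pr <- proj$profile[i]
    if (is.null(pr)) pr <- proj$layer_profile[i]
    if (!pr %in% 1:6) note(id, "layer profile outside 1..6")
    if (!proj$src[i] %in% as.character(seq_along(atlas$region_volumes)) ||
        !proj$tgt[i] %in% as.character(seq_along(atlas$region_volumes))) {
      note(id, "unknown region")
    }
  }
  for (nm in names(recipe$ptypes)) {
    b <- recipe$ptypes[[nm]]
    if (any(b$fractions < 0 | b$fractions > 1)) {
      note(paste("p-type block", nm), "fraction outside [0, 1]")
    }
    if (!is.null(b$interactions) && nrow(b$interactions) &&
        any(b$interactions$increase < 1 - 1e-9)) {
      note(paste("p-type block", nm), "conditional increase below 1")
    }
  }
  if (length(v)) do.call(rbind, v) else {
    data.frame(where = character(), what = character())
  }
}
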