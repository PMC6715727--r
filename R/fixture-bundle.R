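#' Standard synthetic fixture bundle for the full pipeline
#'
#' Generates, from an atlas, every mesoscale input the recipe builder
#' needs: a wild-type projection-strength pair (seeded log-uniform
#' strengths, contralateral at half the ipsilateral strength), per-class
#' module weights, layer-profile frequency tables, a library of six
#' synthetic prototype profiles (each peaking in a different depth band),
#' and projection tensors with planted topographic mappings for the
#' requested region pairs.
#'
#' @param ab atlas bundle from [build_synthetic_atlas()].
#' @param tensor_pairs list of `c(src, tgt)` region id pairs to equip
#'   with planted-mapping tensors (default: regions 1 to 2).
#' @param kernel_width planted kernel width in micrometers.
#' @param noise_sd tensor noise level.
#' @param seed integer seed.
#' @return list with `wt`, `class_module_weights`, `tables`, `library`,
#'   `tensors`, `planted_mappings`.
#' @export
demo_fixture <- function(ab, tensor_pairs = list(c(1, 2)),
                         kernel_width = 60, noise_sd = 0, seed = 0) {
  atlas <- ab$atlas; flatmap <- ab$flatmap
  R <- atlas$n_regions_per_hemisphere
  base <- as.character(seq_len(R))
  classes <- c("L2/3", "L4", "L5IT", "L5PT", "L6")
  mods <- sort(unique(atlas$modules))
  nm <- length(mods)

  local_seed(derive_seed(seed, "matrices"), {
    ipsi <- matrix(10^stats::runif(R * R, -2, 0), R, R,
                   dimnames = list(base, base))
    diag(ipsi) <- 0
    contra <- ipsi / 2
    wt <- projection_matrix(ipsi, contra)

    w <- lapply(classes, function(cl) {
      matrix(stats::runif(nm * nm, 0.2, 1), nm, nm,
             dimnames = list(as.character(mods), as.character(mods)))
    })
    names(w) <- classes

    cf <- matrix(stats::runif(5 * 6, 0.2, 1), 5, 6,
                 dimnames = list(classes, as.character(1:6)))
    cf <- cf / rowSums(cf)
    mf <- array(stats::runif(nm * 2 * 6, 0.2, 1), c(nm, 2, 6),
                dimnames = list(as.character(mods), c("intra", "inter"),
                                as.character(1:6)))
    for (i in seq_len(nm)) for (j in 1:2) {
      mf[i, j, ] <- mf[i, j, ] / sum(mf[i, j, ])
    }
    pc <- array(stats::rpois(nm * 5 * 2, 4) + 1L, c(nm, 5, 2),
                dimnames = list(as.character(mods), classes,
                                c("intra", "inter")))
    tables <- frequency_tables(cf, mf, pc)

    nl <- atlas$n_layers
    prof <- matrix(0.1, 6, nl)
    for (p in 1:6) {
      prof[p, 1 + ((p - 1) %% nl)] <- 2
      prof[p, 1 + (p %% nl)] <- 1
    }
    library <- profile_library(prof, layer_thicknesses(atlas))
    list(wt = wt, class_module_weights = w, tables = tables,
         library = library)
  }) -> fx

  fx$planted_mappings <- list()
  fx$tensors <- list()
  for (pr in tensor_pairs) {
    key <- paste0(pr[1], "->", pr[2])
    src_mask <- region_flat_mask(atlas, flatmap, pr[1])
    tgt_mask <- region_flat_mask(atlas, flatmap, pr[2])
    src_sys <- fit_source_anchors(src_mask)
    tgt_sys <- fit_source_anchors(tgt_mask)
    planted <- topo_mapping(src_sys, tgt_sys, kernel_width = kernel_width)
    fx$planted_mappings[[key]] <- planted
    fx$tensors[[key]] <- synth_projection_tensor(
      atlas, flatmap, planted, pr[1], pr[2], base_strength = 1,
      noise_sd = noise_sd, seed = derive_seed(seed, paste0("tensor-", key)))
  }
  fx
}
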