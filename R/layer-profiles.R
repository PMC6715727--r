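#' Library of prototype laminar synapse-density profiles
#'
#' Six prototype profiles of relative synapse density per cortical layer.
#' Each profile is normalized so its thickness-weighted mean over depth is
#' 1; profiles 1, 3, 5 are the feedforward-associated prototypes and 2, 4,
#' 6 the feedback-associated ones.
#'
#' @param profiles 6 x n_layers non-negative matrix (one row per profile).
#' @param thickness layer thicknesses in micrometers (recycled).
#' @param normalize if TRUE (default) rescale each row to thickness-
#'   weighted mean 1; if FALSE, validate instead.
#' @return object of class `profile_library`.
#' @export
profile_library <- function(profiles, thickness = 1, normalize = TRUE) {
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == 6, all(profiles >= 0))
  thickness <- rep(thickness, length.out = ncol(profiles))
  wm <- as.numeric(profiles %*% thickness) / sum(thickness)
  if (normalize) {
    if (any(wm <= 0)) stop("profile with zero mass cannot be normalized")
    profiles <- profiles / wm
  } else if (any(abs(wm - 1) > 1e-9)) {
    stop("profiles must have thickness-weighted mean 1")
  }
  rownames(profiles) <- as.character(1:6)
  structure(list(profiles = profiles, thickness = thickness,
                 ff_profiles = c(1L, 3L, 5L), fb_profiles = c(2L, 4L, 6L)),
            class = "profile_library")
}

#' Frequency tables for layer-profile prediction
#'
#' @param class_freq matrix classes x 6, per-class relative frequencies of
#'   the six profiles (rows sum to 1).
#' @param module_freq array `[module, intra/inter, profile]` of observed
#'   per-source-module profile frequencies (slices sum to 1).
#' @param projection_counts array `[module, class, intra/inter]` of counts
#'   of projections above the strength cutoff.
#' @return object of class `frequency_tables`.
#' @export
frequency_tables <- function(class_freq, module_freq, projection_counts) {
  class_freq <- as.matrix(class_freq)
  stopifnot(ncol(class_freq) == 6, dim(module_freq)[3] == 6)
  if (any(abs(rowSums(class_freq) - 1) > 1e-9)) {
    stop("class frequency vectors must sum to 1")
  }
  sl <- apply(module_freq, c(1, 2), sum)
  if (any(abs(sl - 1) > 1e-9)) {
    stop("module frequency vectors must sum to 1")
  }
  structure(list(class_freq = class_freq, module_freq = module_freq,
                 projection_counts = projection_counts),
            class = "frequency_tables")
}

#' Expected profile frequencies for a source module
#'
#' Weighted average of the per-class profile-frequency vectors, weighted by
#' the number of (above-cutoff) projections of each class leaving the
#' module, separately for intra- and inter-module projections. The result
#' is a convex combination, so it sums to 1.
#'
#' @param module module id (index into the tables).
#' @param intra_or_inter `"intra"` or `"inter"`.
#' @param tables a `frequency_tables`.
#' @return 6-vector of expected frequencies.
#' @export
expected_frequencies <- function(module, intra_or_inter, tables) {
  ii <- match.arg(intra_or_inter, c("intra", "inter"))
  counts <- tables$projection_counts[as.character(module), , ii]
  if (is.null(names(counts))) {
    names(counts) <- dimnames(tables$projection_counts)[[2]]
  }
  if (sum(counts) <= 0) {
    stop("no projections counted for module ", module, " (", ii, ")")
  }
  as.numeric(counts %*% tables$class_freq[names(counts), , drop = FALSE]) /
    sum(counts)
}

#' Adjustment factors from observed vs expected frequencies
#'
#' Elementwise observed / expected. Where both are 0 the factor is 1 (no
#' evidence either way); observed > 0 with expected 0 is an error.
#'
#' @param observed,expected 6-vectors summing to 1.
#' @return 6-vector of adjustment factors.
#' @export
adjustment_factors <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  if (abs(sum(observed) - 1) > 1e-6 || abs(sum(expected) - 1) > 1e-6) {
    stop("frequency vectors must sum to 1")
  }
  out <- numeric(length(observed))
  zz <- expected == 0
  if (any(zz & observed > 0)) {
    stop("observed frequency > 0 where expected frequency is 0")
  }
  out[zz] <- 1
  out[!zz] <- observed[!zz] / expected[!zz]
  out
}

#' Feedforward / feedback classification of a projection
#'
#' A projection is feedforward iff the source region sits lower in the
#' cortical hierarchy than the target; ties count as feedforward.
#'
#' @param source_region,target_region region ids.
#' @param hierarchy_score named vector region -> hierarchy score.
#' @return `"feedforward"` or `"feedback"`.
#' @export
classify_ff_fb <- function(source_region, target_region, hierarchy_score) {
  s <- hierarchy_score[as.character(source_region)]
  t <- hierarchy_score[as.character(target_region)]
  if (is.na(s) || is.na(t)) stop("missing hierarchy score")
  if (s <= t) "feedforward" else "feedback"
}

#' Assign a prototype layer profile to every projection
#'
#' For each surviving projection: compute adjustment factors for its source
#' module (observed over expected frequencies), halve the factors of the
#' profiles belonging to the opposite direction type (feedback prototypes
#' 2, 4, 6 for a feedforward projection; feedforward prototypes 1, 3, 5
#' for a feedback one), multiply by the class's own frequency vector, and
#' pick the argmax. Ties break toward the lowest profile id. Deterministic.
#'
#' @param projections data.frame with columns `class`, `src`, `tgt` (region
#'   ids as used in `modules`/`hierarchy_score`).
#' @param tables a `frequency_tables`.
#' @param library a `profile_library`.
#' @param modules named vector region -> module.
#' @param hierarchy_score named vector region -> hierarchy score.
#' @return the input data.frame with columns `direction` and `profile`
#'   (integer 1..6) appended.
#' @export
assign_profiles <- function(projections, tables, library, modules,
                            hierarchy_score) {
  n <- nrow(projections)
  profile <- integer(n)
  direction <- character(n)
  for (r in seq_len(n)) {
    src <- projections$src[r]; tgt <- projections$tgt[r]
    cl <- projections$class[r]
    mod <- modules[as.character(src)]
    ii <- if (identical(modules[as.character(src)],
                        modules[as.character(tgt)])) "intra" else "inter"
    expected <- expected_frequencies(mod, ii, tables)
    observed <- tables$module_freq[as.character(mod), ii, ]
    adj <- adjustment_factors(observed, expected)
    dir <- classify_ff_fb(src, tgt, hierarchy_score)
    other <- if (dir == "feedforward") library$fb_profiles else
      library$ff_profiles
    adj[other] <- adj[other] * 0.5
    adjusted <- tables$class_freq[cl, ] * adj
    profile[r] <- which.max(adjusted)  # ties -> lowest id
    direction[r] <- dir
  }
  projections$direction <- direction
  projections$profile <- profile
  projections
}

#' Z-scores of a predicted profile against raw experimental profiles
#'
#' Per layer, `z = (prediction - mean(raw)) / sd(raw)`. Requires at least 5
#' raw profiles; otherwise the projection is skipped with a warning and
#' `NULL` is returned.
#'
#' @param predicted numeric profile vector (length = layers).
#' @param raw matrix of raw profiles (rows = experiments).
#' @return list with per-layer `z`, and `fraction_within_2` (share of
#'   layers with |z| < 2), or `NULL` if fewer than 5 experiments.
#' @export
profile_zscores <- function(predicted, raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 5) {
    warning("fewer than 5 raw profiles; projection skipped")
    return(NULL)
  }
  stopifnot(ncol(raw) == length(predicted))
  mu <- colMeans(raw)
  sdv <- apply(raw, 2, stats::sd)
  z <- (predicted - mu) / sdv
  list(z = z, fraction_within_2 = mean(abs(z) < 2))
}
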