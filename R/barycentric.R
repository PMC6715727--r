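#' Barycentric coordinate system over three anchor points
#'
#' Three non-collinear 2-D anchor points define affine (barycentric)
#' coordinates in the plane; anchor `i` has coordinate vector `e_i`, and by
#' convention coordinate 1/2/3 drives the red/green/blue colour channel of
#' projection images. Coordinates of any point sum to 1; points outside the
#' triangle have negative components.
#'
#' @param anchors 3 x 2 numeric matrix of anchor points (micrometers).
#' @return an object of class `bary_system`.
#' @export
bary_system <- function(anchors) {
  anchors <- as.matrix(anchors)
  stopifnot(nrow(anchors) == 3, ncol(anchors) == 2)
  area2 <- signed_area2(anchors)
  if (abs(area2) < 1e-9) stop("anchor points are collinear or degenerate")
  structure(list(anchors = anchors), class = "bary_system")
}

# twice the signed area of the anchor triangle
signed_area2 <- function(a) {
  (a[2, 1] - a[1, 1]) * (a[3, 2] - a[1, 2]) -
    (a[3, 1] - a[1, 1]) * (a[2, 2] - a[1, 2])
}

#' @export
print.bary_system <- function(x, ...) {
  cat("Barycentric system, anchors (um):\n")
  print(round(x$anchors, 2))
  invisible(x)
}

#' Cartesian to barycentric coordinates
#' @param sys a `bary_system`.
#' @param pts n x 2 matrix of points.
#' @return n x 3 matrix of barycentric coordinates (rows sum to 1).
#' @export
to_bary <- function(sys, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  a <- sys$anchors
  # solve [a1 a2 a3; 1 1 1] b = [p; 1] for each point
  M <- rbind(t(a), rep(1, 3))
  rhs <- rbind(t(pts), rep(1, nrow(pts)))
  t(solve(M, rhs))
}

#' Barycentric to cartesian coordinates
#' @param sys a `bary_system`.
#' @param b n x 3 matrix of barycentric coordinates.
#' @return n x 2 matrix of points.
#' @export
from_bary <- function(sys, b) {
  b <- matrix(as.numeric(b), ncol = 3)
  b %*% sys$anchors
}

#' Pick source anchors inside a region mask
#'
#' Selects the three mask pixels maximizing the sum of pairwise distances
#' (the search can be restricted to convex-hull vertices: the sum of
#' pairwise distances is a convex function of each point, so each maximizer
#' lies at a hull vertex), then moves each 25% of the way toward the mask
#' centroid. Ties are broken by lexicographic pixel order.
#'
#' @param mask data.frame with pixel center columns `x`, `y` (micrometers),
#'   as returned by [region_flat_mask()].
#' @param shrink fraction of the way each anchor is moved toward the mask
#'   centroid (default 0.25).
#' @param use_hull restrict the triple search to convex-hull vertices
#'   (default TRUE; FALSE forces the exhaustive search, used for testing).
#' @return a `bary_system`.
#' @export
fit_source_anchors <- function(mask, shrink = 0.25, use_hull = TRUE) {
  pts <- as.matrix(mask[, c("x", "y")])
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  if (nrow(pts) < 3) stop("mask has fewer than 3 pixels")
  cand <- if (use_hull && nrow(pts) > 3) {
    h <- grDevices::chull(pts)
    pts[sort(h), , drop = FALSE]
  } else pts
  n <- nrow(cand)
  if (n < 3) stop("degenerate mask: fewer than 3 hull vertices")
  D <- as.matrix(stats::dist(cand))
  best <- NULL
  best_val <- -Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    val <- D[i, j] + D[i, k] + D[j, k]
    if (val > best_val + 1e-12) {
      best_val <- val
      best <- c(i, j, k)
    }
  }
  if (best_val <= 1e-9) stop("mask pixels are collinear")
  centroid <- colMeans(pts)
  anchors <- cand[best, , drop = FALSE]
  anchors <- anchors + shrink * (matrix(centroid, 3, 2, byrow = TRUE) - anchors)
  bary_system(anchors)
}
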