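#' 3D alpha-shape of a point set
#'
#' Computes the Delaunay tetrahedralization of the points and retains the
#' tetrahedra whose circumscribed-sphere radius is at most `alpha` (the
#' alpha-complex). Their union is the shape — possibly disconnected, and
#' converging to the convex hull as `alpha` grows. `alpha` is the
#' circumradius threshold in meters; 0.5 m is a good default for leaf-off
#' tree crowns from TLS (sensible band roughly 0.3–1.0 m).
#'
#' @param points A `point_cloud` or 3-column matrix with at least 4 points
#'   in general position.
#' @param alpha Circumradius threshold in meters (default 0.5).
#' @return An `alpha_shape_3d`: list with `vertices` (n x 3 matrix),
#'   `tetra` (m x 4 vertex indices of retained tetrahedra), `circumradius`,
#'   `tet_volume` (per retained tetrahedron), `alpha`, `volume` (total),
#'   `hull_volume` (volume at alpha = Inf).
#' @export
alpha_shape_3d <- function(points, alpha = 0.5) {
  stopifnot(alpha > 0)
  m <- if (inherits(points, "point_cloud")) {
    cbind(points$x, points$y, points$z)
  } else {
    as.matrix(points)[, 1:3, drop = FALSE]
  }
  storage.mode(m) <- "double"
  if (nrow(m) < 4) stop("degenerate for 3D alpha shape: fewer than 4 points")
  dn <- .delaunay3d_cpp(m)
  if (sum(dn$volume) <= 0)
    stop("degenerate for 3D alpha shape: points are coplanar")
  keep <- which(dn$circumradius <= alpha)
  structure(list(vertices = m,
                 tetra = dn$tetra[keep, , drop = FALSE],
                 circumradius = dn$circumradius[keep],
                 tet_volume = dn$volume[keep],
                 alpha = alpha,
                 volume = sum(dn$volume[keep]),
                 hull_volume = sum(dn$volume),
                 all_tetra = dn$tetra,
                 all_circumradius = dn$circumradius,
                 all_volume = dn$volume),
            class = "alpha_shape_3d")
}

#' @exportS3Method base::print
print.alpha_shape_3d <- function(x, ...) {
  cat(sprintf(
    "alpha_shape_3d: alpha = %.3g m, %d/%d tetrahedra, volume %.4f m^3 (hull %.4f)\n",
    x$alpha, nrow(x$tetra), nrow(x$all_tetra), x$volume, x$hull_volume))
  invisible(x)
}

#' Re-threshold an alpha shape at a different alpha
#'
#' Reuses the stored tetrahedralization, so sweeping alpha is cheap.
#'
#' @param shape An `alpha_shape_3d`.
#' @param alpha New circumradius threshold in meters.
#' @return An `alpha_shape_3d` at the new threshold.
#' @export
update_alpha <- function(shape, alpha) {
  stopifnot(inherits(shape, "alpha_shape_3d"), alpha > 0)
  keep <- which(shape$all_circumradius <= alpha)
  shape$tetra <- shape$all_tetra[keep, , drop = FALSE]
  shape$circumradius <- shape$all_circumradius[keep]
  shape$tet_volume <- shape$all_volume[keep]
  shape$alpha <- alpha
  shape$volume <- sum(shape$all_volume[keep])
  shape
}
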