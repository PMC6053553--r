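#' Voxel grid specification
#'
#' Defines the shared plot-global voxel grid: an origin snapped to voxel
#' multiples, a cubic voxel edge length (default 10 cm, i.e. 0.001 m^3 per
#' voxel), and the maximum analyzed height above ground (default 10.3 m).
#' All trees and census years of a plot must share one spec so that voxel
#' indices are comparable across trees and years; [voxel_grid_spec_for()]
#' derives one from the coregistered plot extent.
#'
#' @param origin Numeric length-3 grid origin `(x0, y0, z0)` in meters.
#' @param voxel_size Voxel edge length in meters (default 0.10).
#' @param max_height_above_ground Upper analysis bound in meters above
#'   ground (default 10.3).
#' @return A `voxel_grid_spec`.
#' @export
voxel_grid_spec <- function(origin = c(0, 0, 0), voxel_size = 0.10,
                            max_height_above_ground = 10.3) {
  stopifnot(voxel_size > 0, max_height_above_ground > 0,
            length(origin) == 3)
  structure(list(origin = as.numeric(origin), voxel_size = voxel_size,
                 max_height_above_ground = max_height_above_ground),
            class = "voxel_grid_spec")
}

#' @exportS3Method base::print
print.voxel_grid_spec <- function(x, ...) {
  cat(sprintf(
    "voxel_grid_spec: %.3g m voxels (%.4g m^3), origin (%.2f, %.2f, %.2f), up to %.1f m above ground\n",
    x$voxel_size, voxel_volume(x), x$origin[1], x$origin[2], x$origin[3],
    x$max_height_above_ground))
  invisible(x)
}

#' Volume of a single voxel
#' @param grid A `voxel_grid_spec`.
#' @return Voxel volume in cubic meters (`voxel_size^3`).
#' @export
voxel_volume <- function(grid) grid$voxel_size^3

#' Derive the shared grid spec for a set of clouds
#'
#' Origin is the floor of the joint bounding box to voxel multiples, so all
#' trees and years of the (coregistered) plot index into the same grid.
#'
#' @param clouds A list of `point_cloud`s (all years, after coregistration).
#' @param voxel_size Voxel edge length in meters.
#' @param max_height_above_ground Upper analysis bound in meters.
#' @return A `voxel_grid_spec`.
#' @export
voxel_grid_spec_for <- function(clouds, voxel_size = 0.10,
                                max_height_above_ground = 10.3) {
  if (inherits(clouds, "point_cloud")) clouds <- list(clouds)
  mins <- sapply(clouds, function(p) c(min(p$x), min(p$y), min(p$z)))
  origin <- floor(apply(mins, 1, min) / voxel_size) * voxel_size
  voxel_grid_spec(origin, voxel_size, max_height_above_ground)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-12))
}

#' Voxel index of coordinates (half-open cells)
#'
#' `floor((coord - origin) / voxel_size)` per axis; a point exactly on a
#' cell boundary belongs to the higher cell.
#'
#' @param grid A `voxel_grid_spec`.
#' @param x,y,z Coordinate vectors in meters.
#' @return A `data.table` with integer columns `i`, `j`, `k`.
#' @export
voxel_index <- function(grid, x, y, z) {
  data.table::data.table(
    i = as.integer(floor((x - grid$origin[1]) / grid$voxel_size)),
    j = as.integer(floor((y - grid$origin[2]) / grid$voxel_size)),
    k = as.integer(floor((z - grid$origin[3]) / grid$voxel_size)))
}

#' Voxel center coordinates of indices
#' @param grid A `voxel_grid_spec`.
#' @param i,j,k Integer index vectors.
#' @return A `data.table` with `x`, `y`, `z` center coordinates.
#' @export
voxel_center <- function(grid, i, j, k) {
  s <- grid$voxel_size
  data.table::data.table(x = grid$origin[1] + (i + 0.5) * s,
                         y = grid$origin[2] + (j + 0.5) * s,
                         z = grid$origin[3] + (k + 0.5) * s)
}

#' Direct voxelization of a point cloud
#'
#' Returns the set of distinct voxels containing at least one point.
#'
#' @param cloud A `point_cloud`.
#' @param grid A `voxel_grid_spec`.
#' @return A `data.table` of unique `(i, j, k)` indices.
#' @export
voxelize_points <- function(cloud, grid) {
  stopifnot(inherits(grid, "voxel_grid_spec"))
  if (!nrow(cloud)) {
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  k = integer(0)))
  }
  unique(voxel_index(grid, cloud$x, cloud$y, cloud$z))
}

#' Voxelization of a 3D alpha-shape
#'
#' A voxel is included iff its center lies inside (or on the boundary of,
#' within a 1e-9 barycentric tolerance) any retained tetrahedron of the
#' shape.
#'
#' @param shape An `alpha_shape_3d`.
#' @param grid A `voxel_grid_spec`.
#' @return A `data.table` of unique `(i, j, k)` indices.
#' @export
voxelize_alpha_shape <- function(shape, grid) {
  stopifnot(inherits(shape, "alpha_shape_3d"),
            inherits(grid, "voxel_grid_spec"))
  if (!nrow(shape$tetra)) {
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  k = integer(0)))
  }
  idx <- .voxelize_tetra_cpp(shape$vertices, shape$tetra,
                             grid$origin, grid$voxel_size, 1e-9)
  data.table::data.table(i = idx[, 1], j = idx[, 2], k = idx[, 3])
}
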