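#' Tree position from a stem slice circle fit
#'
#' Cuts a thin horizontal slice of the stem at a given height above ground
#' (default 5 cm, 2 cm thick) and fits a circle to the slice's (x, y) by the
#' algebraic Kasa least-squares fit. The circle center is the tree position;
#' the DTM elevation at the center is attached for later height leveling.
#'
#' @param tree_cloud A `point_cloud` of one tree (stem included).
#' @param dtm A filled `terrain_raster`.
#' @param slice_height Slice center height above ground in meters (default
#'   0.05).
#' @param slice_thickness Slice thickness in meters (default 0.02).
#' @param tree_id,year Identifiers carried into the result.
#' @return A `tree_position`: one-row `data.table` with `tree_id`, `year`,
#'   `x`, `y`, `ground_z`, `radius`, `n_slice`.
#' @export
fit_stem_circle <- function(tree_cloud, dtm, slice_height = 0.05,
                            slice_thickness = 0.02, tree_id = NA, year = NA) {
  stopifnot(inherits(tree_cloud, "point_cloud"))
  hag <- height_above_ground(dtm, tree_cloud$x, tree_cloud$y, tree_cloud$z)
  sel <- hag >= slice_height - slice_thickness / 2 &
         hag <= slice_height + slice_thickness / 2
  xs <- tree_cloud$x[sel]
  ys <- tree_cloud$y[sel]
  if (length(xs) < 3)
    stop("no stem slice: fewer than 3 points at the slice height")
  if (abs(stats::sd(xs)) < 1e-12 && abs(stats::sd(ys)) < 1e-12)
    stop("degenerate stem slice: points coincide")
  fit <- kasa_circle(xs, ys)
  if (!is.finite(fit$r)) stop("degenerate (collinear) stem slice")
  if (fit$r <= 0 || fit$r >= 1)
    warning(sprintf("fitted stem radius %.3f m outside the plausible range",
                    fit$r))
  gz <- dtm_elevation(dtm, fit$cx, fit$cy)
  out <- data.table::data.table(tree_id = tree_id, year = year,
                                x = fit$cx, y = fit$cy, ground_z = gz,
                                radius = fit$r, n_slice = length(xs))
  data.table::setattr(out, "class",
                      c("tree_position", class(data.table::data.table())))
  out
}

# algebraic (Kasa) circle fit: linear least squares on x^2 + y^2
kasa_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) rep(NA_real_, 3))
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  list(cx = unname(sol[1]), cy = unname(sol[2]),
       r = if (is.na(r2) || r2 < 0) NA_real_ else sqrt(unname(r2)))
}

#' Least-squares 2D conformal (similarity) transform between censuses
#'
#' Estimates the 4-parameter planar similarity (uniform scale, rotation,
#' translation) mapping the moving year's tree positions onto the reference
#' year's, matched by `tree_id`. The model is linear in
#' `(a, b, tx, ty) = (s cos r, s sin r, tx, ty)` and solved in closed form.
#' Trees present in only one census are dropped with a warning. Both scans
#' are metric, so a warning is emitted when `|scale - 1| > 0.01`.
#'
#' @param ref,mov `tree_position` tables (or data.frames with `tree_id`,
#'   `x`, `y`) for the reference and moving census.
#' @return A `conformal2d` object: list with `scale`, `rotation` (radians),
#'   `tx`, `ty`, `dz` (0 until [align_heights()]), `mean_residual`,
#'   `rms_residual`, `n` (matched pairs).
#' @export
estimate_conformal_2d <- function(ref, mov) {
  ids <- intersect(ref$tree_id, mov$tree_id)
  if (length(ids) < 2)
    stop("need at least 2 tree positions matched by tree_id")
  dropped <- setdiff(union(ref$tree_id, mov$tree_id), ids)
  if (length(dropped))
    warning(sprintf("%d tree(s) present in only one census dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  r <- as.data.frame(ref)[match(ids, ref$tree_id), c("x", "y")]
  m <- as.data.frame(mov)[match(ids, mov$tree_id), c("x", "y")]
  if (max(stats::dist(m)) < 1e-12 || max(stats::dist(r)) < 1e-12)
    stop("degenerate configuration: positions coincide")
  # ref_x = a*x - b*y + tx ; ref_y = b*x + a*y + ty
  n <- length(ids)
  A <- rbind(cbind(m$x, -m$y, rep(1, n), rep(0, n)),
             cbind(m$y,  m$x, rep(0, n), rep(1, n)))
  rhs <- c(r$x, r$y)
  sol <- qr.solve(A, rhs)
  a <- sol[1]; b <- sol[2]
  tf <- structure(list(scale = sqrt(a^2 + b^2), rotation = atan2(b, a),
                       tx = sol[3], ty = sol[4], dz = 0,
                       mean_residual = NA_real_, rms_residual = NA_real_,
                       n = n),
                  class = "conformal2d")
  pred <- transform_xy(tf, m$x, m$y)
  res <- sqrt((pred$x - r$x)^2 + (pred$y - r$y)^2)
  tf$mean_residual <- mean(res)
  tf$rms_residual <- sqrt(mean(res^2))
  if (abs(tf$scale - 1) > 0.01)
    warning(sprintf("estimated scale %.4f deviates from 1 by more than 1%%",
                    tf$scale))
  tf
}

#' @exportS3Method base::print
print.conformal2d <- function(x, ...) {
  cat(sprintf(paste0("conformal2d: scale %.6f, rotation %.4f rad, ",
                     "t = (%.3f, %.3f) m, dz = %.3f m\n"),
              x$scale, x$rotation, x$tx, x$ty, x$dz))
  if (is.finite(x$mean_residual))
    cat(sprintf("  residuals over %d pairs: mean %.4f m, rms %.4f m\n",
                x$n, x$mean_residual, x$rms_residual))
  invisible(x)
}

transform_xy <- function(tf, x, y) {
  ca <- cos(tf$rotation); sa <- sin(tf$rotation)
  list(x = tf$scale * (ca * x - sa * y) + tf$tx,
       y = tf$scale * (sa * x + ca * y) + tf$ty)
}

#' Vertical leveling between censuses
#'
#' Projects tree positions onto each census' DTM and returns the difference
#' of the plot-mean ground levels, `dz = mean(ref ground) - mean(mov
#' ground)`, to be added to the moving census' heights.
#'
#' @param ref,mov `tree_position` tables with `ground_z` populated.
#' @param transform Optional `conformal2d` to store `dz` into.
#' @return If `transform` is given, the updated transform; otherwise `dz`.
#' @export
align_heights <- function(ref, mov, transform = NULL) {
  if (!nrow(ref) || !nrow(mov)) stop("empty tree position set")
  dz <- mean(ref$ground_z) - mean(mov$ground_z)
  if (is.null(transform)) return(dz)
  transform$dz <- dz
  transform
}

#' Apply a conformal transform to a point cloud
#'
#' Maps `(x, y)` through scale/rotation/translation and shifts `z` by `dz`.
#'
#' @param cloud A `point_cloud`.
#' @param tf A `conformal2d`.
#' @return The transformed `point_cloud` (same point count and order).
#' @export
apply_transform <- function(cloud, tf) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(tf, "conformal2d"))
  xy <- transform_xy(tf, cloud$x, cloud$y)
  point_cloud(xy$x, xy$y, cloud$z + tf$dz,
              intensity = if ("intensity" %in% names(cloud)) cloud$intensity,
              label = attr(cloud, "label"))
}

#' Invert a conformal transform
#' @param tf A `conformal2d`.
#' @return The inverse `conformal2d` (residual fields unset).
#' @export
invert_transform <- function(tf) {
  structure(list(scale = 1 / tf$scale, rotation = -tf$rotation,
                 tx = -(cos(-tf$rotation) * tf$tx -
                          sin(-tf$rotation) * tf$ty) / tf$scale,
                 ty = -(sin(-tf$rotation) * tf$tx +
                          cos(-tf$rotation) * tf$ty) / tf$scale,
                 dz = -tf$dz, mean_residual = NA_real_,
                 rms_residual = NA_real_, n = NA_integer_),
            class = "conformal2d")
}

#' Build a conformal transform from explicit parameters
#' @param scale Uniform scale (default 1).
#' @param rotation Rotation in radians (default 0).
#' @param tx,ty Planar translation in meters.
#' @param dz Vertical shift in meters.
#' @return A `conformal2d`.
#' @export
conformal2d <- function(scale = 1, rotation = 0, tx = 0, ty = 0, dz = 0) {
  stopifnot(scale > 0)
  structure(list(scale = scale, rotation = rotation, tx = tx, ty = ty,
                 dz = dz, mean_residual = NA_real_, rms_residual = NA_real_,
                 n = NA_integer_),
            class = "conformal2d")
}

#' Serialize / deserialize a conformal transform as JSON
#' @param tf A `conformal2d`.
#' @param path File path.
#' @return `path` invisibly (write) or a `conformal2d` (read).
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(unclass(tf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(v, class = "conformal2d")
}
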