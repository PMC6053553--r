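#' Split a tree cloud into crown and stem at the crown base height
#'
#' Points whose height above ground (at their own (x, y) column of the DTM)
#' is at least `cbh` are crown points; the rest are stem points. CBH comes
#' from conventional field inventories and is measured as height above
#' ground at the tree position.
#'
#' @param tree_cloud A `point_cloud`.
#' @param cbh Crown base height in meters above ground.
#' @param dtm A filled `terrain_raster`.
#' @return A list with `crown` and `stem` point clouds (either may be
#'   empty); counts sum to the input count.
#' @export
split_crown_stem <- function(tree_cloud, cbh, dtm) {
  stopifnot(inherits(tree_cloud, "point_cloud"), cbh > 0)
  if (!npoints(tree_cloud)) stop("empty tree cloud")
  hag <- height_above_ground(dtm, tree_cloud$x, tree_cloud$y, tree_cloud$z)
  lbl <- attr(tree_cloud, "label")
  list(crown = structure_cloud(tree_cloud[hag >= cbh], lbl),
       stem = structure_cloud(tree_cloud[hag < cbh], lbl))
}

#' Build the merged voxel-grid tree model
#'
#' Combines the two crown representations — voxelized 3D alpha-shape of the
#' crown points, capturing enclosed (shaded) crown space, and direct
#' voxelization of the crown points, capturing branches protruding beyond
#' the shape — with the directly voxelized stem. On a stem/crown collision
#' the crown label wins (crown volume and intersection volume are crown
#' quantities). The per-voxel `source` records whether a crown voxel came
#' from the alpha-shape, the points, or both.
#'
#' @param crown,stem `point_cloud`s from [split_crown_stem()].
#' @param grid A `voxel_grid_spec` shared by the whole plot.
#' @param alpha Alpha-shape circumradius threshold in meters (default 0.5).
#' @param tree_id,species,year Tree metadata carried into the model.
#' @param cbh Crown base height in meters (metadata).
#' @return A `tree_voxel_model`: `data.table` of unique `(i, j, k)` with
#'   `compartment` ("crown"/"stem") and `source` ("alpha"/"points"/"both"),
#'   plus metadata attributes.
#' @export
build_tree_model <- function(crown, stem, grid, alpha = 0.5,
                             tree_id = NA, species = NA, year = NA,
                             cbh = NA_real_) {
  stopifnot(inherits(grid, "voxel_grid_spec"))
  if ((is.null(crown) || !nrow(crown)) && (is.null(stem) || !nrow(stem)))
    stop("both crown and stem are empty")

  crown_pts <- voxelize_points(crown, grid)
  crown_alpha <- if (!is.null(crown) && nrow(crown) >= 4) {
    shape <- tryCatch(alpha_shape_3d(crown, alpha), error = function(e) NULL)
    if (is.null(shape)) {
      warning("crown is degenerate for a 3D alpha shape; ",
              "using direct voxelization only")
      data.table::data.table(i = integer(0), j = integer(0), k = integer(0))
    } else {
      voxelize_alpha_shape(shape, grid)
    }
  } else {
    if (!is.null(crown) && nrow(crown) > 0)
      warning("fewer than 4 crown points; alpha shape skipped, ",
              "direct voxelization still applied")
    data.table::data.table(i = integer(0), j = integer(0), k = integer(0))
  }

  crown_pts[, src_pts := TRUE]
  crown_alpha[, src_alpha := TRUE]
  cr <- merge(crown_pts, crown_alpha, by = c("i", "j", "k"), all = TRUE)
  cr[, `:=`(compartment = "crown",
            source = data.table::fcase(
              !is.na(src_pts) & !is.na(src_alpha), "both",
              !is.na(src_pts), "points",
              default = "alpha"))]
  cr[, c("src_pts", "src_alpha") := NULL]

  st <- voxelize_points(stem, grid)
  st[, `:=`(compartment = "stem", source = "points")]
  # crown label wins on collisions
  st <- st[!cr, on = c("i", "j", "k")]

  model <- data.table::rbindlist(list(cr, st), use.names = TRUE)
  data.table::setorder(model, i, j, k)
  data.table::setattr(model, "class",
                      c("tree_voxel_model", class(data.table::data.table())))
  data.table::setattr(model, "grid", grid)
  data.table::setattr(model, "tree_id", tree_id)
  data.table::setattr(model, "species", species)
  data.table::setattr(model, "year", year)
  data.table::setattr(model, "cbh", cbh)
  model
}

#' @exportS3Method base::print
print.tree_voxel_model <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf(
    "tree_voxel_model: tree %s (%s), year %s: %d voxels (%d crown, %d stem) of %.3g m\n",
    attr(x, "tree_id"), attr(x, "species"), attr(x, "year"), nrow(x),
    sum(x$compartment == "crown"), sum(x$compartment == "stem"),
    g$voxel_size))
  invisible(x)
}

#' Model a whole tree from its cloud
#'
#' Convenience wrapper: [split_crown_stem()] then [build_tree_model()].
#'
#' @param tree_cloud A `point_cloud` of one segmented tree.
#' @param cbh Crown base height in meters above ground.
#' @param dtm A filled `terrain_raster`.
#' @param grid A `voxel_grid_spec`.
#' @param alpha Alpha-shape threshold in meters.
#' @param tree_id,species,year Metadata.
#' @return A `tree_voxel_model`.
#' @export
model_tree <- function(tree_cloud, cbh, dtm, grid, alpha = 0.5,
                       tree_id = NA, species = NA, year = NA) {
  parts <- split_crown_stem(tree_cloud, cbh, dtm)
  build_tree_model(parts$crown, parts$stem, grid, alpha = alpha,
                   tree_id = tree_id, species = species, year = year,
                   cbh = cbh)
}

#' Write / read a tree voxel model as CSV
#'
#' The CSV carries `(tree_id, species, year, cbh, i, j, k, compartment,
#' source)` plus a commented grid-spec header.
#'
#' @param model A `tree_voxel_model`.
#' @param path File path.
#' @return `path` invisibly (write); a `tree_voxel_model` (read).
#' @export
write_tree_model <- function(model, path) {
  g <- attr(model, "grid")
  hdr <- sprintf(
    "# grid origin %.9g %.9g %.9g voxel_size %.9g max_hag %.9g",
    g$origin[1], g$origin[2], g$origin[3], g$voxel_size,
    g$max_height_above_ground)
  meta <- sprintf("# tree_id %s species %s year %s cbh %.9g",
                  attr(model, "tree_id"), attr(model, "species"),
                  attr(model, "year"), attr(model, "cbh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, meta), con)
  utils::write.csv(as.data.frame(model), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_model
#' @export
read_tree_model <- function(path) {
  hdr <- readLines(path, n = 2)
  gv <- as.numeric(strsplit(hdr[1], "\\s+")[[1]][c(4, 5, 6, 8, 10)])
  mv <- strsplit(hdr[2], "\\s+")[[1]]
  dt <- data.table::fread(path, skip = 2)
  build_args <- list(grid = voxel_grid_spec(gv[1:3], gv[4], gv[5]),
                     tree_id = mv[3], species = mv[5], year = mv[7],
                     cbh = as.numeric(mv[9]))
  data.table::setattr(dt, "class",
                      c("tree_voxel_model", class(data.table::data.table())))
  data.table::setattr(dt, "grid", build_args$grid)
  data.table::setattr(dt, "tree_id", build_args$tree_id)
  data.table::setattr(dt, "species", build_args$species)
  data.table::setattr(dt, "year", build_args$year)
  data.table::setattr(dt, "cbh", build_args$cbh)
  dt
}
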