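#' Pipeline configuration
#'
#' Central parameter set for the full workflow, with defaults matching
#' standard survey practice for dense young-stand TLS campaigns: 10 cm
#' voxels, alpha 0.5 m, 5 cm DTM cells, 1 cm subsampling, outlier filter
#' k = 10 / sigma = 1.5, stem slice at 5 cm (2 cm thick), 10.3 m height
#' cap, 6 m investigation square.
#'
#' @param voxel_size Voxel edge length in meters.
#' @param alpha Alpha-shape circumradius threshold in meters.
#' @param dtm_cell DTM cell size in meters.
#' @param min_dist Subsampling minimum spacing in meters.
#' @param outlier_k,outlier_sigma Statistical outlier filter parameters.
#' @param slice_height,slice_thickness Stem slice definition in meters.
#' @param max_height_above_ground Analysis height cap in meters.
#' @param area_size Investigation-area side length in meters.
#' @param layers Optional data.frame of canopy layers (`name`, `z_low`,
#'   `z_high`); `NULL` derives the two default 1-m layers from the truth.
#' @param seed Seed for synthetic inputs.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size = 0.10, alpha = 0.5,
                            dtm_cell = 0.05, min_dist = 0.01,
                            outlier_k = 10, outlier_sigma = 1.5,
                            slice_height = 0.05, slice_thickness = 0.02,
                            max_height_above_ground = 10.3,
                            area_size = 6, layers = NULL, seed = 1) {
  cfg <- list(voxel_size = voxel_size, alpha = alpha, dtm_cell = dtm_cell,
              min_dist = min_dist, outlier_k = outlier_k,
              outlier_sigma = outlier_sigma, slice_height = slice_height,
              slice_thickness = slice_thickness,
              max_height_above_ground = max_height_above_ground,
              area_size = area_size, layers = layers, seed = seed)
  if (any(unlist(cfg[c("voxel_size", "alpha", "dtm_cell", "min_dist",
                       "slice_height", "slice_thickness",
                       "max_height_above_ground", "area_size")]) <= 0))
    stop("all lengths in the configuration must be positive")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(unlist(cfg)), unlist(cfg), sep = "="), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Executes filter -> DTM -> (register if two censuses) -> per-tree model
#' -> plot grid -> occupancy statistics -> change detection, writing all
#' tables plus a machine-readable run manifest into `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param scene A `scene` (census 1), or a `scene_spec` from which one is
#'   generated.
#' @param scene2 Optional second-census `scene` (e.g. from
#'   [offset_scene_year2()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `table` (the occupancy table), `dtm`,
#'   `grid`, `area`, `cv` (per-tree crown volumes), `civ`, `occupancy`,
#'   `transform` and `change` (two-census runs only), and `manifest_path`.
#' @export
run_pipeline <- function(config, scene, scene2 = NULL, out_dir = tempfile()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(scene, "scene_spec")) scene <- generate_scene(scene)
  if (!inherits(scene, "scene")) stop("scene must be a scene or scene_spec")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...)
    message(sprintf("[canvox %s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))

  clean <- function(pc) {
    pc <- spatial_subsample(pc, config$min_dist)
    if (npoints(pc) > config$outlier_k)
      pc <- remove_statistical_outliers(pc, config$outlier_k,
                                        config$outlier_sigma)
    pc
  }

  log_stage("filtering census-1 clouds (%d trees)", length(scene$trees))
  trees1 <- lapply(scene$trees, clean)
  ground1 <- spatial_subsample(scene$ground, config$min_dist)
  dtm1 <- fill_gaps(extract_dtm(ground1, config$dtm_cell))

  years <- 1
  transform <- NULL
  trees2 <- NULL
  if (!is.null(scene2)) {
    log_stage("filtering census-2 clouds and coregistering")
    trees2_raw <- lapply(scene2$trees, clean)
    ground2 <- spatial_subsample(scene2$ground, config$min_dist)
    dtm2 <- fill_gaps(extract_dtm(ground2, config$dtm_cell))
    pos1 <- data.table::rbindlist(lapply(names(trees1), function(id)
      fit_stem_circle(trees1[[id]], dtm1, config$slice_height,
                      config$slice_thickness, tree_id = id, year = 1)))
    pos2 <- data.table::rbindlist(lapply(names(trees2_raw), function(id)
      fit_stem_circle(trees2_raw[[id]], dtm2, config$slice_height,
                      config$slice_thickness, tree_id = id, year = 2)))
    transform <- estimate_conformal_2d(pos1, pos2)
    transform <- align_heights(pos1, pos2, transform)
    trees2 <- lapply(trees2_raw, apply_transform, tf = transform)
    write_transform(transform, file.path(out_dir, "transform.json"))
    data.table::fwrite(rbind(pos1, pos2),
                       file.path(out_dir, "tree_positions.csv"))
    years <- c(1, 2)
  }

  log_stage("building voxel grid tree models (alpha = %.2f, s = %.2f m)",
            config$alpha, config$voxel_size)
  grid <- voxel_grid_spec_for(c(trees1, trees2, list(ground1)),
                              config$voxel_size,
                              config$max_height_above_ground)
  truth <- scene$truth
  mk_models <- function(trees, year) {
    lapply(names(trees), function(id) {
      cbh <- truth$cbh[truth$tree_id == id]
      sp <- truth$species[truth$tree_id == id]
      model_tree(trees[[id]], cbh, dtm1, grid, alpha = config$alpha,
                 tree_id = id, species = sp, year = year)
    })
  }
  models <- mk_models(trees1, 1)
  if (!is.null(trees2)) models <- c(models, mk_models(trees2, 2))

  table <- build_occupancy_table(models, dtm1, grid)
  write_occupancy_table(table, file.path(out_dir, "occupancy_table.csv"))

  log_stage("plot statistics")
  area <- investigation_area_around(truth, size = config$area_size,
                                    height = config$max_height_above_ground)
  cv <- data.table::rbindlist(lapply(years, function(yy)
    data.table::data.table(
      tree_id = truth$tree_id,
      year = yy,
      cv_m3 = vapply(truth$tree_id, function(id) {
        if (nrow(table[tree_id == id & year == yy]))
          crown_volume(table, id, yy) else NA_real_
      }, 0))))
  civ <- data.table::rbindlist(lapply(years, function(yy)
    data.table::rbindlist(lapply(truth$tree_id, function(id) {
      if (!nrow(table[tree_id == id & year == yy])) return(NULL)
      v <- crown_intersection_volume(table, id, yy)
      data.table::data.table(tree_id = id, year = yy,
                             civ_total = v$civ_total,
                             civ_intra = v$civ_intra,
                             civ_inter = v$civ_inter)
    }))))
  occ <- data.table::rbindlist(lapply(years, function(yy)
    data.table::data.table(year = yy,
                           occupancy_volumes(table, area, yy))))
  data.table::fwrite(cv, file.path(out_dir, "crown_volumes.csv"))
  data.table::fwrite(civ, file.path(out_dir, "crown_intersection.csv"))
  data.table::fwrite(occ, file.path(out_dir, "occupancy_volumes.csv"))

  change <- NULL
  if (length(years) == 2) {
    change <- change_detection(table, 1, 2, area)
    data.table::fwrite(attr(change, "summary"),
                       file.path(out_dir, "change_summary.csv"))
    heatmap_export(change, file.path(out_dir, "change_heatmap.csv"), area)
  }

  manifest <- list(package = "canvox",
                   version = as.character(utils::packageVersion("canvox")),
                   config = unclass(config)[!vapply(config, is.null, TRUE)],
                   config_hash = config_hash(config),
                   n_trees = length(scene$trees),
                   years = years,
                   outputs = list.files(out_dir))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  log_stage("done: %s", out_dir)
  invisible(list(table = table, dtm = dtm1, grid = grid, area = area,
                 cv = cv, civ = civ, occupancy = occ,
                 transform = transform, change = change,
                 manifest_path = manifest_path))
}
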