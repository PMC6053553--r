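#' Assemble the plot-level voxel-grid data table
#'
#' Adds each tree's voxel model to the (conceptually empty) plot grid. Every
#' (voxel, tree, year) pair becomes one record, so canopy space shared by
#' two or more trees shows up as several records at the same unique voxel
#' position — the occupancy fold of a voxel-year is its number of distinct
#' tree ids. Voxel height above ground is the voxel-center z minus the DTM
#' elevation of the voxel's column; voxels above the grid's
#' `max_height_above_ground` are excluded.
#'
#' @param models A list of `tree_voxel_model`s sharing one grid spec.
#' @param dtm A filled `terrain_raster`.
#' @param grid The shared `voxel_grid_spec`.
#' @return An `occupancy_table`: long-format `data.table` with columns
#'   `tree_id`, `species`, `year`, `compartment`, `source`, `i`, `j`, `k`,
#'   `x_center`, `y_center`, `z_center`, `height_above_ground`; the grid and
#'   DTM ride along as attributes.
#' @export
build_occupancy_table <- function(models, dtm, grid) {
  stopifnot(inherits(grid, "voxel_grid_spec"), inherits(dtm, "terrain_raster"))
  if (inherits(models, "tree_voxel_model")) models <- list(models)
  for (m in models) {
    if (!same_grid(attr(m, "grid"), grid))
      stop("all tree models must share the same voxel grid spec")
  }
  recs <- data.table::rbindlist(lapply(models, function(m) {
    dt <- data.table::data.table(tree_id = attr(m, "tree_id"),
                                 species = attr(m, "species"),
                                 year = attr(m, "year"),
                                 compartment = m$compartment,
                                 source = m$source,
                                 i = m$i, j = m$j, k = m$k)
    dt
  }))
  cc <- voxel_center(grid, recs$i, recs$j, recs$k)
  recs[, `:=`(x_center = cc$x, y_center = cc$y, z_center = cc$z)]
  recs[, height_above_ground :=
         z_center - dtm_elevation(dtm, x_center, y_center)]
  recs <- recs[height_above_ground <= grid$max_height_above_ground + 1e-9]
  as_occupancy_table(recs, grid, dtm)
}

as_occupancy_table <- function(dt, grid, dtm) {
  data.table::setattr(dt, "class",
                      c("occupancy_table", class(data.table::data.table())))
  data.table::setattr(dt, "grid", grid)
  data.table::setattr(dt, "dtm", dtm)
  dt
}

#' @exportS3Method base::print
print.occupancy_table <- function(x, ...) {
  cat(sprintf(
    "occupancy_table: %d records, %d voxels, %d trees, years: %s\n",
    nrow(x), data.table::uniqueN(x, by = c("i", "j", "k")),
    data.table::uniqueN(x$tree_id),
    paste(sort(unique(x$year)), collapse = ", ")))
  invisible(x)
}

#' Crown volume of one tree
#'
#' Number of the tree's crown-compartment voxels times the voxel volume.
#'
#' @param table An `occupancy_table`.
#' @param tree Tree id.
#' @param year Census year.
#' @return Crown volume in cubic meters.
#' @export
crown_volume <- function(table, tree, year) {
  yr <- year
  sel <- table[tree_id == tree & year == yr]
  if (!nrow(sel)) stop("unknown tree/year: ", tree, "/", year)
  s <- attr(table, "grid")$voxel_size
  nrow(unique(sel[compartment == "crown", .(i, j, k)])) * s^3
}

#' Crown intersection volume of one tree
#'
#' Over the focal tree's crown voxels occupied by two or more trees (crown
#' compartments only): the total shared volume, its split into volume
#' shared with at least one conspecific (`civ_intra`) and at least one
#' heterospecific neighbor (`civ_inter`), and a breakdown by occupancy fold.
#' A voxel shared with both kinds of neighbor counts once in each of
#' intra/inter but once only in the total.
#'
#' @param table An `occupancy_table`.
#' @param tree Focal tree id.
#' @param year Census year.
#' @return A list: `civ_total`, `civ_intra`, `civ_inter` (m^3), and
#'   `by_fold` — a `data.table` of shared volume per occupancy fold
#'   (`"2"`, `"3"`, `"4+"`).
#' @export
crown_intersection_volume <- function(table, tree, year) {
  yr <- year
  crown <- table[year == yr & compartment == "crown"]
  focal <- crown[tree_id == tree]
  if (!nrow(table[tree_id == tree & year == yr]))
    stop("unknown tree/year: ", tree, "/", year)
  s <- attr(table, "grid")$voxel_size
  sp_focal <- focal$species[1]
  others <- crown[tree_id != tree][focal[, .(i, j, k)], on = c("i", "j", "k"),
                                   nomatch = NULL]
  shared <- others[, .(fold = data.table::uniqueN(tree_id) + 1L,
                       intra = any(species == sp_focal),
                       inter = any(species != sp_focal)),
                   by = .(i, j, k)]
  by_fold <- shared[, .(n = .N), by = .(fold_class = ifelse(fold >= 4, "4+",
                                                            as.character(fold)))]
  by_fold[, volume_m3 := n * s^3]
  list(civ_total = nrow(shared) * s^3,
       civ_intra = sum(shared$intra) * s^3,
       civ_inter = sum(shared$inter) * s^3,
       by_fold = by_fold[order(fold_class)])
}

#' Define an investigation area
#'
#' The analysis region: a square (or rectangular) ground footprint plus a
#' height limit above ground. The canonical setting is 6 m x 6 m x 10.3 m
#' centered on the inner-core tree positions, a space volume of 370.8 m^3.
#'
#' @param xlim,ylim Numeric length-2 planimetric bounds in meters
#'   (half-open: a voxel center belongs to the area iff `xlim[1] <= x <
#'   xlim[2]`, same for y).
#' @param height Height limit above ground in meters (default 10.3;
#'   inclusive).
#' @return An `investigation_area`.
#' @export
investigation_area <- function(xlim, ylim, height = 10.3) {
  stopifnot(length(xlim) == 2, length(ylim) == 2, height > 0,
            diff(xlim) > 0, diff(ylim) > 0)
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 height = height),
            class = "investigation_area")
}

#' @rdname investigation_area
#' @param positions A `tree_position` table (or data.frame with `x`, `y`)
#'   of the inner-core trees to center on.
#' @param size Side length of the square footprint in meters (default 6).
#' @export
investigation_area_around <- function(positions, size = 6, height = 10.3) {
  cx <- mean(positions$x)
  cy <- mean(positions$y)
  investigation_area(cx + c(-0.5, 0.5) * size, cy + c(-0.5, 0.5) * size,
                     height)
}

#' @exportS3Method base::print
print.investigation_area <- function(x, ...) {
  cat(sprintf(
    "investigation_area: x [%.2f, %.2f) x y [%.2f, %.2f) x %.1f m above ground = %.1f m^3\n",
    x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$height, area_volume(x)))
  invisible(x)
}

#' Analytic volume of an investigation area
#' @param area An `investigation_area`.
#' @return Width x depth x height in cubic meters.
#' @export
area_volume <- function(area) {
  diff(area$xlim) * diff(area$ylim) * area$height
}

# Voxel columns of the region and their k-index budget for heights above
# ground in [z_lo, z_hi); the region top (area$height) is inclusive.
region_columns <- function(area, grid, dtm, z_lo = 0, z_hi = NULL) {
  s <- grid$voxel_size
  top_closed <- is.null(z_hi) || z_hi >= area$height - 1e-9
  z_hi <- min(if (is.null(z_hi)) area$height else z_hi, area$height)
  i_rng <- seq.int(ceiling((area$xlim[1] - grid$origin[1]) / s - 0.5 - 1e-9),
                   floor((area$xlim[2] - grid$origin[1]) / s - 0.5 - 1e-9))
  j_rng <- seq.int(ceiling((area$ylim[1] - grid$origin[2]) / s - 0.5 - 1e-9),
                   floor((area$ylim[2] - grid$origin[2]) / s - 0.5 - 1e-9))
  cols <- data.table::CJ(i = i_rng, j = j_rng)
  cc <- voxel_center(grid, cols$i, cols$j, 0L)
  e <- dtm_elevation(dtm, cc$x, cc$y)
  z0 <- grid$origin[3]
  cols[, k_min := as.integer(ceiling((e + z_lo - z0) / s - 0.5 - 1e-9))]
  if (top_closed) {
    cols[, k_max := as.integer(floor((e + z_hi - z0) / s - 0.5 + 1e-9))]
  } else {
    cols[, k_max := as.integer(floor((e + z_hi - z0) / s - 0.5 - 1e-9))]
  }
  cols
}

#' Voxel budget of a region
#'
#' Number of voxel centers whose column lies in the area footprint and whose
#' height above ground falls in `[z_lo, z_hi)` (`[0, height]` by default).
#'
#' @param area An `investigation_area`.
#' @param grid A `voxel_grid_spec`.
#' @param dtm A filled `terrain_raster`.
#' @param z_lo,z_hi Optional height-above-ground stratum bounds in meters.
#' @return Integer voxel count.
#' @export
region_voxel_budget <- function(area, grid, dtm, z_lo = 0, z_hi = NULL) {
  cols <- region_columns(area, grid, dtm, z_lo, z_hi)
  sum(pmax(cols$k_max - cols$k_min + 1L, 0L))
}

#' Clip an occupancy table to an investigation area
#'
#' Keeps records whose voxel center lies in the planimetric bounds
#' (half-open) and whose height above ground is within `[0, height]`.
#'
#' @param table An `occupancy_table`.
#' @param area An `investigation_area`.
#' @return The clipped `occupancy_table` (warning when empty).
#' @export
clip_investigation_area <- function(table, area) {
  stopifnot(inherits(area, "investigation_area"))
  out <- table[x_center >= area$xlim[1] - 1e-9 &
                 x_center < area$xlim[2] - 1e-9 &
                 y_center >= area$ylim[1] - 1e-9 &
                 y_center < area$ylim[2] - 1e-9 &
                 height_above_ground >= -1e-9 &
                 height_above_ground <= area$height + 1e-9]
  if (!nrow(out)) warning("no records inside the investigation area")
  as_occupancy_table(out, attr(table, "grid"), attr(table, "dtm"))
}

#' Voxel volumes per occupancy class
#'
#' Within the investigation area and census year, counts each distinct
#' voxel once at its occupancy fold (number of distinct trees whose crown
#' model contains it; stem-only voxels are not counted) and reports
#' absolute volumes for the classes empty, single, twofold, threefold and
#' fourfold-or-more. Empty volume is the region's voxel budget minus the
#' occupied voxels, times the voxel volume, so the classes always sum to
#' the region's voxel-count volume.
#'
#' @param table An `occupancy_table`.
#' @param area An `investigation_area`.
#' @param year Census year.
#' @param z_lo,z_hi Optional height stratum (see [region_voxel_budget()]).
#' @return A `data.table` with `class` ("empty", "1", "2", "3", "4+"),
#'   `n_voxels` and `volume_m3`.
#' @export
occupancy_volumes <- function(table, area, year, z_lo = 0, z_hi = NULL) {
  yr <- year
  s <- attr(table, "grid")$voxel_size
  clipped <- suppressWarnings(clip_investigation_area(table, area))
  crown <- clipped[year == yr & compartment == "crown"]
  if (!is.null(z_hi) || z_lo > 0) {
    top_closed <- is.null(z_hi) || z_hi >= area$height - 1e-9
    hi <- min(if (is.null(z_hi)) area$height else z_hi, area$height)
    crown <- crown[height_above_ground >= z_lo - 1e-9 &
                     (if (top_closed) height_above_ground <= hi + 1e-9
                      else height_above_ground < hi - 1e-9)]
  }
  folds <- crown[, .(fold = data.table::uniqueN(tree_id)), by = .(i, j, k)]
  cls <- factor(ifelse(folds$fold >= 4, "4+", as.character(folds$fold)),
                levels = c("1", "2", "3", "4+"))
  counts <- table(cls)
  budget <- region_voxel_budget(area, attr(table, "grid"),
                                attr(table, "dtm"), z_lo, z_hi)
  out <- data.table::data.table(
    class = c("empty", names(counts)),
    n_voxels = c(budget - nrow(folds), as.integer(counts)))
  out[, volume_m3 := n_voxels * s^3]
  out
}

#' Aggregate occupancy volumes over canopy layers
#'
#' Computes [occupancy_volumes()] restricted to each horizontal stratum of
#' height above ground (`z_low <= h < z_high`; a stratum reaching the area
#' top includes it). Typical strata are two 1-m layers, one centered on the
#' plot mean tree height (top layer), one on the mean crown center height
#' (middle layer).
#'
#' @param table An `occupancy_table`.
#' @param area An `investigation_area`.
#' @param layers A data.frame with columns `name`, `z_low`, `z_high`
#'   (meters above ground).
#' @param year Census year.
#' @return A `data.table` with `layer`, `z_low`, `z_high`, `class`,
#'   `n_voxels`, `volume_m3`.
#' @export
layer_aggregate <- function(table, area, layers, year) {
  layers <- as.data.frame(layers)
  stopifnot(all(c("name", "z_low", "z_high") %in% names(layers)))
  if (nrow(layers) > 1) {
    o <- order(layers$z_low)
    if (any(layers$z_high[o][-nrow(layers)] >
              layers$z_low[o][-1] + 1e-9))
      warning("layer definitions overlap")
  }
  data.table::rbindlist(lapply(seq_len(nrow(layers)), function(r) {
    ov <- occupancy_volumes(table, area, year,
                            z_lo = layers$z_low[r], z_hi = layers$z_high[r])
    data.table::data.table(layer = layers$name[r], z_low = layers$z_low[r],
                           z_high = layers$z_high[r], ov)
  }))
}

#' Mean-height helpers for canopy layer placement
#'
#' `default_canopy_layers()` returns the two standard 1-m strata: the top
#' layer centered on the mean tree height and the middle layer centered on
#' the mean crown center height, `(cbh + height) / 2`, of the supplied
#' (inner-core) trees.
#'
#' @param heights Tree heights in meters.
#' @param cbh Crown base heights in meters.
#' @param thickness Layer thickness in meters (default 1).
#' @return A data.frame usable as `layers` in [layer_aggregate()].
#' @export
default_canopy_layers <- function(heights, cbh, thickness = 1) {
  top_c <- mean(heights)
  mid_c <- mean((cbh + heights) / 2)
  data.frame(name = c("middle", "top"),
             z_low = c(mid_c, top_c) - thickness / 2,
             z_high = c(mid_c, top_c) + thickness / 2)
}

#' Between-year change detection
#'
#' Per-voxel difference in occupancy fold between two censuses within a
#' mandatory region: `delta = occupancy(year2) - occupancy(year1)`,
#' categorized as increased (`delta > 0`), decreased (`delta < 0`) or
#' unchanged. The evaluation set is the union of voxels occupied in either
#' year inside the region; with `include_empty = TRUE` every voxel of the
#' region's budget is evaluated (never-occupied voxels count as unchanged).
#'
#' @param table An `occupancy_table` holding both years.
#' @param year1,year2 The two census years.
#' @param area An `investigation_area` (mandatory region).
#' @param z_lo,z_hi Optional height stratum restriction.
#' @param include_empty Evaluate never-occupied voxels too? (default FALSE)
#' @return A `change_map`: `data.table` of `(i, j, k, occ1, occ2, delta,
#'   category)` with a `summary` attribute — `data.table` of per-category
#'   voxel counts and percentages (summing to 100).
#' @export
change_detection <- function(table, year1, year2, area, z_lo = 0,
                             z_hi = NULL, include_empty = FALSE) {
  grid <- attr(table, "grid")
  dtm <- attr(table, "dtm")
  clipped <- suppressWarnings(clip_investigation_area(table, area))
  crown <- clipped[compartment == "crown" & year %in% c(year1, year2)]
  if (!is.null(z_hi) || z_lo > 0) {
    top_closed <- is.null(z_hi) || z_hi >= area$height - 1e-9
    hi <- min(if (is.null(z_hi)) area$height else z_hi, area$height)
    crown <- crown[height_above_ground >= z_lo - 1e-9 &
                     (if (top_closed) height_above_ground <= hi + 1e-9
                      else height_above_ground < hi - 1e-9)]
  }
  occ <- crown[, .(occ = data.table::uniqueN(tree_id)), by = .(year, i, j, k)]
  o1 <- occ[year == year1, .(i, j, k, occ1 = occ)]
  o2 <- occ[year == year2, .(i, j, k, occ2 = occ)]
  cm <- merge(o1, o2, by = c("i", "j", "k"), all = TRUE)
  if (include_empty) {
    cols <- region_columns(area, grid, dtm, z_lo, z_hi)
    cols <- cols[k_max >= k_min]
    all_vox <- cols[, .(k = seq.int(k_min, k_max)), by = .(i, j)]
    cm <- merge(all_vox, cm, by = c("i", "j", "k"), all.x = TRUE)
  }
  cm[is.na(occ1), occ1 := 0L]
  cm[is.na(occ2), occ2 := 0L]
  cm[, delta := occ2 - occ1]
  cm[, category := data.table::fcase(delta > 0L, "increased",
                                     delta < 0L, "decreased",
                                     default = "unchanged")]
  summ <- cm[, .(n = .N), by = category]
  summ <- merge(data.table::data.table(category = c("increased", "decreased",
                                                    "unchanged")),
                summ, by = "category", all.x = TRUE)
  summ[is.na(n), n := 0L]
  summ[, pct := if (nrow(cm)) 100 * n / nrow(cm) else NA_real_]
  data.table::setattr(cm, "class",
                      c("change_map", class(data.table::data.table())))
  data.table::setattr(cm, "summary", summ)
  data.table::setattr(cm, "grid", grid)
  data.table::setattr(cm, "years", c(year1, year2))
  cm
}

#' @exportS3Method base::print
print.change_map <- function(x, ...) {
  yrs <- attr(x, "years")
  cat(sprintf("change_map %s -> %s over %d voxels:\n", yrs[1], yrs[2],
              nrow(x)))
  s <- attr(x, "summary")
  for (r in seq_len(nrow(s)))
    cat(sprintf("  %-9s %6d (%.1f%%)\n", s$category[r], s$n[r], s$pct[r]))
  invisible(x)
}

#' Export a planimetric heat map
#'
#' Writes a 2D matrix over the region's voxel columns `(i, j)`. For an
#' `occupancy_table` the cell value is the number of crown records in the
#' column (for a single-voxel-thick stratum this is the voxel's occupancy
#' fold); for a `change_map` it is the net occupancy change summed over the
#' column. Output is a CSV matrix and, optionally, a PNG image.
#'
#' @param x An `occupancy_table` or `change_map`.
#' @param path CSV output path.
#' @param area An `investigation_area` defining the column range.
#' @param year Census year (occupancy tables only).
#' @param z_lo,z_hi Optional height stratum (occupancy tables only).
#' @param png_path Optional PNG output path.
#' @return The matrix, invisibly (rows = x index, cols = y index).
#' @export
heatmap_export <- function(x, path, area, year = NULL, z_lo = 0,
                           z_hi = NULL, png_path = NULL) {
  grid <- attr(x, "grid")
  if (inherits(x, "change_map")) {
    vals <- x[, .(v = sum(delta)), by = .(i, j)]
  } else {
    stopifnot(!is.null(year))
    yr <- year
    clipped <- suppressWarnings(clip_investigation_area(x, area))
    crown <- clipped[year == yr & compartment == "crown"]
    if (!is.null(z_hi) || z_lo > 0) {
      hi <- if (is.null(z_hi)) area$height else z_hi
      crown <- crown[height_above_ground >= z_lo - 1e-9 &
                       height_above_ground < hi - 1e-9]
    }
    vals <- crown[, .(v = .N), by = .(i, j)]
  }
  s <- grid$voxel_size
  i_rng <- seq.int(ceiling((area$xlim[1] - grid$origin[1]) / s - 0.5 - 1e-9),
                   floor((area$xlim[2] - grid$origin[1]) / s - 0.5 - 1e-9))
  j_rng <- seq.int(ceiling((area$ylim[1] - grid$origin[2]) / s - 0.5 - 1e-9),
                   floor((area$ylim[2] - grid$origin[2]) / s - 0.5 - 1e-9))
  m <- matrix(0, nrow = length(i_rng), ncol = length(j_rng),
              dimnames = list(i_rng, j_rng))
  inb <- vals$i %in% i_rng & vals$j %in% j_rng
  m[cbind(match(vals$i[inb], i_rng), match(vals$j[inb], j_rng))] <-
    vals$v[inb]
  utils::write.csv(m, path)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 640, height = 640)
    graphics::image(x = i_rng, y = j_rng, z = m, xlab = "i", ylab = "j",
                    main = "voxel occupancy heat map", useRaster = TRUE)
    grDevices::dev.off()
  }
  invisible(m)
}

#' Write / read an occupancy table as CSV
#'
#' @param table An `occupancy_table`.
#' @param path File path.
#' @return `path` invisibly (write); a plain `data.table` (read).
#' @export
write_occupancy_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_occupancy_table
#' @export
read_occupancy_table <- function(path) {
  data.table::fread(path)
}
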