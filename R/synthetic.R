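#' Specify a synthetic plot scene
#'
#' Describes a procedurally generated experimental plot: trees planted on a
#' regular grid (default 1.29 m spacing, as in large planted biodiversity
#' experiments), with per-tree heights, stem diameters and crown base
#' heights drawn from the given ranges, two crown habits ("broad" spreads
#' wider than the planting distance so neighboring crowns interlock,
#' "narrow" stays mostly within it), and a flat, tilted or undulating
#' ground surface. The same spec and seed always generate the identical
#' scene.
#'
#' @param nrows,ncols Planting grid dimensions (default 20 x 20).
#' @param spacing Planting distance in meters (default 1.29).
#' @param species Character vector of crown habits cycled over the grid in
#'   a checkerboard fashion; entries must be `"broad"` or `"narrow"`.
#' @param height_range Tree height range in meters (default 4–8).
#' @param dbh_range Stem diameter range in meters (default 0.05–0.09).
#' @param cbh_frac_range Crown base height as a fraction of tree height.
#' @param terrain `"flat"`, `"tilted"` (5% slope) or `"undulating"`.
#' @param terrain_amplitude Undulation amplitude in meters (default 0.3).
#' @param angular_step_deg Scanner angular step in degrees (default 0.036,
#'   giving point spacings of 1.3/3.1/6.3 mm at 2/5/10 m).
#' @param noise_sigma Isotropic per-point range noise in meters (default
#'   0.002).
#' @param ground_spacing Ground sampling distance in meters (default 0.04).
#' @param seed Random seed (reproducibility contract).
#' @return A `scene_spec`.
#' @export
scene_spec <- function(nrows = 20, ncols = 20, spacing = 1.29,
                       species = c("broad", "narrow"),
                       height_range = c(4, 8), dbh_range = c(0.05, 0.09),
                       cbh_frac_range = c(0.25, 0.45),
                       terrain = c("flat", "tilted", "undulating"),
                       terrain_amplitude = 0.3,
                       angular_step_deg = 0.036, noise_sigma = 0.002,
                       ground_spacing = 0.04, seed = 1) {
  terrain <- match.arg(terrain)
  stopifnot(spacing > 0, all(height_range > 0), all(dbh_range > 0),
            all(cbh_frac_range > 0 & cbh_frac_range < 1),
            all(species %in% c("broad", "narrow")))
  structure(list(nrows = nrows, ncols = ncols, spacing = spacing,
                 species = species, height_range = height_range,
                 dbh_range = dbh_range, cbh_frac_range = cbh_frac_range,
                 terrain = terrain, terrain_amplitude = terrain_amplitude,
                 angular_step_deg = angular_step_deg,
                 noise_sigma = noise_sigma,
                 ground_spacing = ground_spacing, seed = seed),
            class = "scene_spec")
}

terrain_fun <- function(spec) {
  switch(spec$terrain,
         flat = function(x, y) rep(0, length(x)),
         tilted = function(x, y) 0.05 * x,
         undulating = function(x, y)
           spec$terrain_amplitude * sin(2 * pi * x / 10) *
             cos(2 * pi * y / 10))
}

species_habit <- function(sp) {
  if (sp == "broad") {
    list(crown_radius = 1.15, elev_range = c(5, 35) * pi / 180,
         n_branches = 9)
  } else {
    list(crown_radius = 0.65, elev_range = c(45, 72) * pi / 180,
         n_branches = 7)
  }
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# grow a recursive branching crown; returns a cylinder matrix
# (x0 y0 z0 x1 y1 z1 r level)
grow_crown <- function(x, y, zg, h, cbh, habit) {
  out <- list()
  n1 <- habit$n_branches
  attach_h <- zg + cbh + (h - cbh) * (seq_len(n1) - 0.5) / n1
  for (b in seq_len(n1)) {
    az <- stats::runif(1, 0, 2 * pi)
    el <- stats::runif(1, habit$elev_range[1], habit$elev_range[2])
    # higher branches shorten toward the tip
    taper <- 1 - 0.6 * (b - 1) / n1
    len <- habit$crown_radius * stats::runif(1, 0.8, 1.2) * taper
    segs <- branch_segments(c(x, y, attach_h[b]), az, el, len, 0.015, 1L)
    out[[length(out) + 1L]] <- segs
  }
  do.call(rbind, out)
}

branch_segments <- function(p0, az, el, len, r, level) {
  d <- c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  p1 <- p0 + len * d
  seg <- c(p0, p1, r, level)
  if (level >= 3L || len < 0.15) return(matrix(seg, nrow = 1))
  kids <- lapply(seq_len(sample(2:3, 1)), function(q) {
    branch_segments(p1, az + stats::runif(1, -0.9, 0.9),
                    min(el + stats::runif(1, -0.2, 0.45), pi / 2 - 0.05),
                    len * stats::runif(1, 0.5, 0.7), r * 0.55, level + 1L)
  })
  rbind(matrix(seg, nrow = 1), do.call(rbind, kids))
}

default_scanners <- function(spec) {
  w <- (spec$ncols - 1) * spec$spacing
  d <- (spec$nrows - 1) * spec$spacing
  cx <- w / 2; cy <- d / 2
  ring <- 2.5 + max(w, d) / 2
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  rbind(c(cx, cy, 1.7),
        cbind(cx + ring * cos(ang), cy + ring * sin(ang), 1.7))
}

sample_cylinder <- function(p0, p1, r, spacing, nmax = 250000) {
  axis <- p1 - p0
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) return(NULL)
  u <- axis / len
  # orthonormal frame around the axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  n_ax <- max(2L, ceiling(len / spacing))
  n_circ <- max(3L, ceiling(2 * pi * r / spacing))
  if (n_ax * n_circ > nmax) n_ax <- max(2L, nmax %/% n_circ)
  t_ax <- seq(0, len, length.out = n_ax)
  th <- seq(0, 2 * pi, length.out = n_circ + 1)[-(n_circ + 1)]
  g <- expand.grid(t = t_ax, th = th)
  px <- p0[1] + g$t * u[1] + r * (cos(g$th) * e1[1] + sin(g$th) * e2[1])
  py <- p0[2] + g$t * u[2] + r * (cos(g$th) * e1[2] + sin(g$th) * e2[2])
  pz <- p0[3] + g$t * u[3] + r * (cos(g$th) * e1[3] + sin(g$th) * e2[3])
  cbind(px, py, pz)
}

#' Generate a synthetic plot scene
#'
#' Builds procedural trees (tapered trunk cylinders plus a 3-level recursive
#' branching crown above the crown base height), samples their surfaces at
#' the range-dependent point spacing of a phase-shift scanner
#' (`spacing = range x angular step`, taken from the nearest of nine
#' simulated scan positions, floored at 1 mm), adds isotropic noise, and
#' samples the ground surface. Per-tree clouds are returned separately,
#' emulating the manually segmented single-tree clouds of a real campaign,
#' together with the ground truth needed for recovery tests.
#'
#' @param spec A `scene_spec`.
#' @return A `scene`: list with `spec`, `trees` (named list of
#'   `point_cloud`s), `ground` (`point_cloud`), `truth` (`data.table`:
#'   `tree_id`, `species`, `x`, `y`, `ground_z`, `height`, `dbh`, `cbh`,
#'   `alive`), `primitives` (cylinder matrix for ray casting), `terrain`
#'   (elevation function), `scanners`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    tf <- terrain_fun(spec)
    scanners <- default_scanners(spec)
    theta <- spec$angular_step_deg * pi / 180

    gridpos <- expand.grid(col = seq_len(spec$ncols) - 1,
                           row = seq_len(spec$nrows) - 1)
    n <- nrow(gridpos)
    truth <- data.table::data.table(
      tree_id = sprintf("T%03d", seq_len(n)),
      species = spec$species[((gridpos$col + gridpos$row) %%
                                length(spec$species)) + 1],
      x = gridpos$col * spec$spacing,
      y = gridpos$row * spec$spacing,
      height = stats::runif(n, spec$height_range[1], spec$height_range[2]),
      dbh = stats::runif(n, spec$dbh_range[1], spec$dbh_range[2]),
      cbh_frac = stats::runif(n, spec$cbh_frac_range[1],
                              spec$cbh_frac_range[2]))
    truth[, ground_z := tf(x, y)]
    truth[, cbh := round(height * cbh_frac, 2)]
    truth[, cbh_frac := NULL]
    truth[, alive := TRUE]

    trees <- vector("list", n)
    prims <- vector("list", n)
    for (t in seq_len(n)) {
      x <- truth$x[t]; y <- truth$y[t]
      zg <- truth$ground_z[t]
      h <- truth$height[t]
      r0 <- truth$dbh[t] / 2
      # tapered trunk: three stacked cylinders
      zb <- zg + c(0, 0.45, 0.8) * h
      zt <- zg + c(0.45, 0.8, 1.0) * h
      rr <- r0 * c(1, 0.6, 0.3)
      trunk <- cbind(x, y, zb, x, y, zt, rr, 0L)
      crown <- grow_crown(x, y, zg, h, truth$cbh[t],
                          species_habit(truth$species[t]))
      cyl <- rbind(trunk, unname(crown))
      prims[[t]] <- cbind(cyl, t)
      pts <- lapply(seq_len(nrow(cyl)), function(rw) {
        p0 <- cyl[rw, 1:3]; p1 <- cyl[rw, 4:6]
        mid <- (p0 + p1) / 2
        rng <- sqrt(min(colSums((t(scanners) - mid)^2)))
        sp <- max(rng * theta, 0.001)
        sample_cylinder(p0, p1, cyl[rw, 7], sp)
      })
      m <- do.call(rbind, pts)
      m <- m + matrix(stats::rnorm(length(m), 0, spec$noise_sigma),
                      ncol = 3)
      trees[[t]] <- point_cloud(m[, 1], m[, 2], m[, 3],
                                label = truth$tree_id[t])
    }
    names(trees) <- truth$tree_id

    # ground must cover the widest crown so every tree point has a DTM column
    margin <- 3.0
    gx <- seq(min(truth$x) - margin, max(truth$x) + margin,
              by = spec$ground_spacing)
    gy <- seq(min(truth$y) - margin, max(truth$y) + margin,
              by = spec$ground_spacing)
    gg <- expand.grid(x = gx, y = gy)
    gz <- tf(gg$x, gg$y) + stats::rnorm(nrow(gg), 0, spec$noise_sigma)
    ground <- point_cloud(gg$x, gg$y, gz, label = "ground")

    structure(list(spec = spec, trees = trees, ground = ground,
                   truth = truth,
                   primitives = do.call(rbind, prims),
                   terrain = tf, scanners = scanners),
              class = "scene")
  })
}

#' @exportS3Method base::print
print.scene <- function(x, ...) {
  cat(sprintf(
    "scene: %d trees (%s terrain), %d tree points + %d ground points\n",
    length(x$trees), x$spec$terrain,
    sum(vapply(x$trees, nrow, 0L)), nrow(x$ground)))
  invisible(x)
}

#' Scanner point spacing at range
#'
#' Small-angle arc length `range x angular step`: the spacing between
#' neighboring points a phase-shift scanner places on a surface at the
#' given range. A step of 0.036 degrees yields 1.3, 3.1 and 6.3 mm at 2, 5
#' and 10 m.
#'
#' @param range_m Range(s) in meters.
#' @param angular_step_deg Angular step in degrees (default 0.036).
#' @return Spacing in millimeters, reported to 0.1 mm.
#' @export
scan_point_spacing <- function(range_m, angular_step_deg = 0.036) {
  stopifnot(all(range_m >= 0), angular_step_deg >= 0)
  round(range_m * angular_step_deg * pi / 180 * 1000, 1)
}

#' Simulate a multi-position scan by ray casting
#'
#' Casts rays from each scanner position over an azimuth/elevation fan at
#' the given angular resolution and keeps the first hit on any primitive
#' (occlusion), then adds isotropic noise and uniform stray points. Scan
#' coregistration is assumed perfect (all scanners share the scene frame).
#'
#' @param scene A `scene`, or a primitive matrix: rows
#'   `(type, p1..p9)` with type 0 sphere `(cx cy cz r)`, type 1 cylinder
#'   `(x0 y0 z0 x1 y1 z1 r)`, type 2 rectangle `(corner, edge u, edge v)`.
#' @param scanners Matrix of scanner positions (rows `(x, y, z)`); default
#'   the scene's nine positions.
#' @param angular_step_deg Angular step in degrees. The default for
#'   simulation is 0.2 to keep ray counts tractable; pass 0.036 for
#'   survey-grade sampling of small scenes.
#' @param az_range,el_range Azimuth/elevation fan in degrees.
#' @param noise_sigma Isotropic noise sd in meters.
#' @param stray_rate Fraction of extra uniform stray points (default 0).
#' @return A merged `point_cloud`.
#' @export
simulate_scan <- function(scene, scanners = NULL, angular_step_deg = 0.2,
                          az_range = c(0, 360), el_range = c(-40, 89),
                          noise_sigma = 0, stray_rate = 0) {
  prim <- if (inherits(scene, "scene")) {
    cbind(1, scene$primitives[, 1:7, drop = FALSE],
          matrix(0, nrow(scene$primitives), 2))
  } else {
    as.matrix(scene)
  }
  if (ncol(prim) < 10) {
    prim <- cbind(prim, matrix(0, nrow(prim), 10 - ncol(prim)))
  }
  if (is.null(scanners)) {
    if (!inherits(scene, "scene"))
      stop("scanners must be given when scene is a primitive matrix")
    scanners <- scene$scanners
  }
  scanners <- matrix(as.numeric(scanners), ncol = 3)
  step <- angular_step_deg
  az <- seq(az_range[1], az_range[2] - step / 2, by = step) * pi / 180
  el <- seq(el_range[1], el_range[2], by = step) * pi / 180
  hits <- lapply(seq_len(nrow(scanners)), function(s) {
    h <- .raycast_cpp(prim, scanners[s, ], az, el)
    cbind(h$x, h$y, h$z)
  })
  m <- do.call(rbind, hits)
  if (!nrow(m)) return(point_cloud(numeric(0), numeric(0), numeric(0),
                                   label = "scan"))
  if (noise_sigma > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, noise_sigma), ncol = 3)
  if (stray_rate > 0) {
    ns <- ceiling(stray_rate * nrow(m))
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    stray <- sapply(1:3, function(c) stats::runif(ns, lo[c], hi[c]))
    m <- rbind(m, matrix(stray, ncol = 3))
  }
  point_cloud(m[, 1], m[, 2], m[, 3], label = "scan")
}

#' Derive the second-census scene
#'
#' Applies per-tree growth (vertical stretch of the crown above the crown
#' base and radial expansion about the stem axis), removes trees that died,
#' and expresses everything in a different plot-local frame by applying the
#' INVERSE of the given similarity — so `transform` is exactly what a
#' correct coregistration must recover. The true transform is stored in the
#' result for recovery tests.
#'
#' @param scene A `scene` (census year 1).
#' @param transform A `conformal2d`: the year2 -> year1 mapping to be
#'   recovered later.
#' @param growth_height Height increment(s) in meters (scalar or per tree;
#'   default 0.3).
#' @param growth_crown Relative radial crown expansion (default 0.08).
#' @param mortality Character vector of tree ids that died (default none).
#' @return The year-2 `scene`; `truth` has updated heights and `alive`
#'   flags, and the list carries `truth_transform`.
#' @export
offset_scene_year2 <- function(scene, transform = conformal2d(),
                               growth_height = 0.3, growth_crown = 0.08,
                               mortality = character(0)) {
  stopifnot(inherits(scene, "scene"), inherits(transform, "conformal2d"))
  inv <- invert_transform(transform)
  truth <- data.table::copy(scene$truth)
  gh <- rep_len(growth_height, nrow(truth))
  trees <- scene$trees
  for (t in seq_len(nrow(truth))) {
    id <- truth$tree_id[t]
    if (id %in% mortality) {
      truth[t, alive := FALSE]
      trees[[id]] <- NULL
      next
    }
    pc <- trees[[id]]
    x0 <- truth$x[t]; y0 <- truth$y[t]
    zb <- truth$ground_z[t] + truth$cbh[t]
    h0 <- truth$height[t]
    fz <- (h0 + gh[t] - truth$cbh[t]) / (h0 - truth$cbh[t])
    up <- pc$z > zb
    nx <- pc$x; ny <- pc$y; nz <- pc$z
    nz[up] <- zb + (nz[up] - zb) * fz
    nx[up] <- x0 + (nx[up] - x0) * (1 + growth_crown)
    ny[up] <- y0 + (ny[up] - y0) * (1 + growth_crown)
    trees[[id]] <- point_cloud(nx, ny, nz, label = attr(pc, "label"))
    truth[t, height := h0 + gh[t]]
  }
  trees <- lapply(trees, apply_transform, tf = inv)
  ground <- apply_transform(scene$ground, inv)
  out <- scene
  out$trees <- trees
  out$ground <- ground
  out$truth <- truth
  out$primitives <- NULL
  out$truth_transform <- transform
  out
}
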