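#' Digital terrain model by lowest-point rasterization
#'
#' Overlays a horizontal raster (default cell 5 cm) on the cloud's xy
#' bounding box and keeps the lowest z per cell, the usual leaf-off TLS
#' ground-extraction rule. Cells without points are `NA` until
#' [fill_gaps()] is applied. Binning is half-open,
#' `[x0 + i*c, x0 + (i+1)*c)`, with the origin snapped down to a cell
#' multiple — the same convention as the voxel grid.
#'
#' @param cloud A non-empty `point_cloud` (the filtered merged plot cloud).
#' @param cell_size Raster cell size in meters (default 0.05).
#' @return A `terrain_raster`: list with `origin`, `cell_size`, `elev`
#'   matrix (rows = x index, cols = y index), and `filled` flag.
#' @export
extract_dtm <- function(cloud, cell_size = 0.05) {
  stopifnot(inherits(cloud, "point_cloud"), cell_size > 0)
  if (!npoints(cloud)) stop("cannot build a DTM from an empty cloud")
  x0 <- floor(min(cloud$x) / cell_size) * cell_size
  y0 <- floor(min(cloud$y) / cell_size) * cell_size
  i <- floor((cloud$x - x0) / cell_size)
  j <- floor((cloud$y - y0) / cell_size)
  ni <- max(i) + 1L
  nj <- max(j) + 1L
  dt <- data.table::data.table(i = i, j = j, z = cloud$z)
  mins <- dt[, .(z = min(z)), by = .(i, j)]
  elev <- matrix(NA_real_, nrow = ni, ncol = nj)
  elev[cbind(mins$i + 1L, mins$j + 1L)] <- mins$z
  structure(list(origin = c(x0, y0), cell_size = cell_size, elev = elev,
                 filled = FALSE, method = NA_character_),
            class = "terrain_raster")
}

#' @exportS3Method base::print
print.terrain_raster <- function(x, ...) {
  cat(sprintf(
    "terrain_raster: %d x %d cells of %.3g m, origin (%.2f, %.2f), %s\n",
    nrow(x$elev), ncol(x$elev), x$cell_size, x$origin[1], x$origin[2],
    if (x$filled) sprintf("filled (%s)", x$method) else
      sprintf("%d empty cells", sum(is.na(x$elev)))))
  invisible(x)
}

cell_centers <- function(raster) {
  list(x = raster$origin[1] + (seq_len(nrow(raster$elev)) - 0.5) * raster$cell_size,
       y = raster$origin[2] + (seq_len(ncol(raster$elev)) - 0.5) * raster$cell_size)
}

#' Fill empty DTM cells by interpolation from neighboring cells
#'
#' Empty cells are filled from the observed cells around them. The default
#' `"harmonic"` method solves the discrete Laplace equation over the
#' missing cells with observed cells as boundary values (sparse direct
#' solve): smooth in the interior, exact for affine ground surfaces, fast
#' and deterministic even for large rasters, and it extends smoothly past
#' the observed footprint. The alternatives interpolate over the scattered
#' observed cell centers via [interp::interp()] — `"linear"` (barycentric,
#' also exact on affine surfaces) or `"akima"` (C1 spline) — with cells
#' outside the convex footprint set to the nearest observed cell; both are
#' practical only for modest rasters because the triangulation backend
#' degrades on strictly gridded input. Observed cells are never modified.
#'
#' @param raster A `terrain_raster` with at least 3 non-collinear observed
#'   cells.
#' @param method `"harmonic"` (default), `"linear"` or `"akima"`.
#' @return The filled `terrain_raster`; the method used is recorded in its
#'   `method` field.
#' @export
fill_gaps <- function(raster, method = c("harmonic", "linear", "akima")) {
  stopifnot(inherits(raster, "terrain_raster"))
  method <- match.arg(method)
  obs <- which(!is.na(raster$elev), arr.ind = TRUE)
  if (nrow(obs) < 3) stop("need at least 3 observed cells to interpolate")
  cc <- cell_centers(raster)
  ox <- cc$x[obs[, 1]]
  oy <- cc$y[obs[, 2]]
  oz <- raster$elev[obs]
  if (abs(stats::sd(ox)) < 1e-12 || abs(stats::sd(oy)) < 1e-12 ||
      abs(suppressWarnings(stats::cor(ox, oy))) > 1 - 1e-12)
    stop("observed cells are collinear; cannot interpolate a surface")
  miss <- which(is.na(raster$elev), arr.ind = TRUE)
  out <- raster
  if (nrow(miss)) {
    zi <- if (method == "harmonic") {
      fill_harmonic(raster$elev, miss)
    } else {
      fill_scattered(raster, miss, ox, oy, oz, cc, method)
    }
    out$elev[miss] <- zi
  }
  out$filled <- TRUE
  out$method <- method
  out
}

# discrete Laplace solve: 4-neighbour graph, observed cells Dirichlet,
# raster edge Neumann (degree = number of in-raster neighbours)
fill_harmonic <- function(elev, miss) {
  ni <- nrow(elev); nj <- ncol(elev)
  nm <- nrow(miss)
  id <- matrix(0L, ni, nj)
  id[miss] <- seq_len(nm)
  deg <- numeric(nm)
  b <- numeric(nm)
  ii <- list(); jj <- list(); xx <- list()
  shifts <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (s in shifts) {
    nr <- miss[, 1] + s[1]
    nc <- miss[, 2] + s[2]
    inside <- nr >= 1L & nr <= ni & nc >= 1L & nc <= nj
    deg[inside] <- deg[inside] + 1
    nb_lin <- (nc[inside] - 1L) * ni + nr[inside]
    nb_id <- id[nb_lin]
    nb_val <- elev[nb_lin]
    m_obs <- nb_id == 0L
    w <- which(inside)
    b[w[m_obs]] <- b[w[m_obs]] + nb_val[m_obs]
    ii[[length(ii) + 1L]] <- w[!m_obs]
    jj[[length(jj) + 1L]] <- nb_id[!m_obs]
    xx[[length(xx) + 1L]] <- rep(-1, sum(!m_obs))
  }
  A <- Matrix::sparseMatrix(i = c(seq_len(nm), unlist(ii)),
                            j = c(seq_len(nm), unlist(jj)),
                            x = c(deg, unlist(xx)), dims = c(nm, nm))
  as.numeric(Matrix::solve(A, b))
}

fill_scattered <- function(raster, miss, ox, oy, oz, cc, method) {
  mx <- cc$x[miss[, 1]]
  my <- cc$y[miss[, 2]]
  zi <- withCallingHandlers(
    interp::interp(x = ox, y = oy, z = oz, xo = mx, yo = my,
                   output = "points", method = method)$z,
    warning = function(w) {
      if (grepl("shull", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # outside the convex footprint the interpolant is NA: nearest observed cell
  nas <- which(is.na(zi))
  if (length(nas)) {
    nn <- .nn1_2d_cpp(mx[nas], my[nas], ox, oy)
    zi[nas] <- oz[nn]
  }
  zi
}

#' Ground elevation at planimetric positions
#'
#' @param raster A filled `terrain_raster`.
#' @param x,y Query coordinates (vectors, meters).
#' @return Elevation of the cell containing each `(x, y)`.
#' @export
dtm_elevation <- function(raster, x, y) {
  stopifnot(inherits(raster, "terrain_raster"))
  if (!raster$filled) stop("raster must be gap-filled first (fill_gaps)")
  i <- floor((x - raster$origin[1]) / raster$cell_size) + 1L
  j <- floor((y - raster$origin[2]) / raster$cell_size) + 1L
  # clamp boundary queries landing exactly on the max edge
  i[i == nrow(raster$elev) + 1L & x <= raster$origin[1] +
      nrow(raster$elev) * raster$cell_size + 1e-9] <- nrow(raster$elev)
  j[j == ncol(raster$elev) + 1L & y <= raster$origin[2] +
      ncol(raster$elev) * raster$cell_size + 1e-9] <- ncol(raster$elev)
  if (any(i < 1L | i > nrow(raster$elev) | j < 1L | j > ncol(raster$elev)))
    stop("query position outside the raster extent")
  raster$elev[cbind(i, j)]
}

#' Height above ground
#'
#' `z` minus the DTM elevation of the raster cell containing `(x, y)` —
#' the per-column normalization used for all voxel heights.
#'
#' @param raster A filled `terrain_raster`.
#' @param x,y,z Query coordinates (vectors, meters).
#' @return Heights above ground in meters.
#' @export
height_above_ground <- function(raster, x, y, z) {
  z - dtm_elevation(raster, x, y)
}

#' Write a terrain raster as an ESRI ASCII grid
#'
#' @param raster A `terrain_raster`.
#' @param path Output path.
#' @param nodata NODATA marker (default -9999).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "terrain_raster"))
  e <- raster$elev
  hdr <- c(sprintf("ncols %d", nrow(e)),
           sprintf("nrows %d", ncol(e)),
           sprintf("xllcorner %.6f", raster$origin[1]),
           sprintf("yllcorner %.6f", raster$origin[2]),
           sprintf("cellsize %.6f", raster$cell_size),
           sprintf("NODATA_value %s", format(nodata)))
  # ESRI rows run north -> south: row r of the file is y index (nj - r + 1)
  body <- vapply(rev(seq_len(ncol(e))), function(j) {
    v <- e[, j]
    v[is.na(v)] <- nodata
    paste(format(v, digits = 9, scientific = FALSE, trim = TRUE),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a terrain raster
#'
#' @param path Path to the grid file.
#' @return A `terrain_raster` (unfilled if NODATA cells are present).
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- as.integer(val("ncols"))
  nrows <- as.integer(val("nrows"))
  nodata <- val("NODATA_value")
  body <- lines[-(1:6)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  elev <- matrix(NA_real_, nrow = ncols, ncol = nrows)
  for (r in seq_len(nrows)) {
    j <- nrows - r + 1L
    elev[, j] <- vals[((r - 1) * ncols + 1):(r * ncols)]
  }
  elev[elev == nodata] <- NA_real_
  structure(list(origin = c(val("xllcorner"), val("yllcorner")),
                 cell_size = val("cellsize"), elev = elev,
                 filled = !anyNA(elev), method = NA_character_),
            class = "terrain_raster")
}
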