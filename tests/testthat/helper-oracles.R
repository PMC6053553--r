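# Brute-force oracles and small fixtures shared across tests.

# mean distance to the k nearest neighbours, O(n^2)
bf_knn_mean <- function(m, k) {
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  apply(d, 1, function(r) mean(sort(r)[seq_len(k)]))
}

# minimum pairwise distance of a cloud
min_pair_dist <- function(pc) {
  d <- stats::dist(cbind(pc$x, pc$y, pc$z))
  if (!length(d)) Inf else min(d)
}

# per-point voxel index by direct floor computation
bf_voxel_index <- function(m, origin, s) {
  unique(data.table::data.table(
    i = as.integer(floor((m[, 1] - origin[1]) / s)),
    j = as.integer(floor((m[, 2] - origin[2]) / s)),
    k = as.integer(floor((m[, 3] - origin[3]) / s))))
}

# is point p inside tetra (rows of q), barycentric with tolerance
bf_in_tetra <- function(p, q, tol = 1e-9) {
  A <- t(q[2:4, , drop = FALSE]) - matrix(q[1, ], 3, 3)
  l <- tryCatch(solve(A, p - q[1, ]), error = function(e) return(c(-1, -1, -1)))
  all(l >= -tol) && sum(l) <= 1 + tol
}

# voxel centers inside any tetra, exhaustive over the tetra bounding boxes
bf_voxelize_tetra <- function(verts, tetra, origin, s, tol = 1e-9) {
  out <- list()
  for (t in seq_len(nrow(tetra))) {
    q <- verts[tetra[t, ], , drop = FALSE]
    rng <- lapply(1:3, function(c) {
      seq.int(floor((min(q[, c]) - origin[c]) / s - 1),
              ceiling((max(q[, c]) - origin[c]) / s + 1))
    })
    g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
    ctr <- cbind(origin[1] + (g$i + 0.5) * s,
                 origin[2] + (g$j + 0.5) * s,
                 origin[3] + (g$k + 0.5) * s)
    ins <- vapply(seq_len(nrow(ctr)),
                  function(r) bf_in_tetra(ctr[r, ], q, tol), TRUE)
    out[[t]] <- g[ins, ]
  }
  unique(data.table::rbindlist(out))
}

# circumsphere of a tetra (rows of q): list(center, r)
bf_circumsphere <- function(q) {
  A <- 2 * (q[2:4, ] - matrix(q[1, ], 3, 3, byrow = TRUE))
  b <- rowSums(q[2:4, ]^2) - sum(q[1, ]^2)
  cc <- solve(A, b)
  list(center = cc, r = sqrt(sum((q[1, ] - cc)^2)))
}

# exact points on a circle (optionally an arc)
circle_points <- function(n, cx, cy, r, arc = c(0, 2 * pi), z = 0) {
  th <- seq(arc[1], arc[2], length.out = n + 1)[seq_len(n)]
  point_cloud(cx + r * cos(th), cy + r * sin(th), rep(z, n))
}

# a filled flat DTM at elevation z0 covering [-e, e]^2
flat_dtm <- function(z0 = 0, extent = 12, cell = 0.05) {
  g <- expand.grid(x = seq(-extent, extent, cell),
                   y = seq(-extent, extent, cell))
  fill_gaps(extract_dtm(point_cloud(g$x, g$y, rep(z0, nrow(g))), cell))
}

# hand-made voxel model: a tree occupying the given (i,j,k) rows
toy_model <- function(vox, grid, tree_id, species = "broad", year = 1,
                      compartment = "crown") {
  dt <- data.table::data.table(i = vox[, 1], j = vox[, 2], k = vox[, 3],
                               compartment = compartment, source = "points")
  data.table::setattr(dt, "class",
                      c("tree_voxel_model", class(data.table::data.table())))
  data.table::setattr(dt, "grid", grid)
  data.table::setattr(dt, "tree_id", tree_id)
  data.table::setattr(dt, "species", species)
  data.table::setattr(dt, "year", year)
  data.table::setattr(dt, "cbh", 1)
  dt
}

# small fast scene for pipeline-level tests: coarse sampling keeps point
# counts in the tens of thousands
small_scene_spec <- function(seed = 1, nrows = 2, ncols = 2, ...) {
  scene_spec(nrows = nrows, ncols = ncols, angular_step_deg = 0.3,
             seed = seed, ...)
}

expect_same_voxels <- function(a, b) {
  key <- c("i", "j", "k")
  a <- data.table::setorderv(data.table::as.data.table(a)[, key, with = FALSE], key)
  b <- data.table::setorderv(data.table::as.data.table(b)[, key, with = FALSE], key)
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
}
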