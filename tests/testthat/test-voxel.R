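test_that("voxel grid spec: volume and index conventions", {
  g <- voxel_grid_spec(c(0, 0, 0), 0.10)
  expect_equal(voxel_volume(g), 0.001)

  # single point at the origin
  expect_equal(as.data.frame(voxelize_points(point_cloud(0, 0, 0), g)),
               data.frame(i = 0L, j = 0L, k = 0L))
  # boundary point goes to the higher cell (half-open rule)
  idx <- voxel_index(g, 0.1, 0, 0)
  expect_equal(idx$i, 1L)

  # centers invert indices
  ctr <- voxel_center(g, 3L, -2L, 0L)
  expect_equal(as.numeric(ctr), c(0.35, -0.15, 0.05))
  expect_equal(as.data.frame(voxel_index(g, ctr$x, ctr$y, ctr$z)),
               data.frame(i = 3L, j = -2L, k = 0L))
})

test_that("direct voxelization matches the brute-force floor computation", {
  set.seed(44)
  g <- voxel_grid_spec(c(-1, 2, 0.3), 0.07)
  m <- cbind(runif(1000, -1, 3), runif(1000, 2, 5), runif(1000, 0.3, 4))
  pc <- point_cloud(m[, 1], m[, 2], m[, 3])
  expect_same_voxels(voxelize_points(pc, g), bf_voxel_index(m, g$origin, 0.07))
})

test_that("alpha-shape voxelization: aligned cube yields exactly 10^3 voxels", {
  pts <- as.matrix(expand.grid(seq(0, 1, 0.25), seq(0, 1, 0.25),
                               seq(0, 1, 0.25)))
  sh <- alpha_shape_3d(pts, alpha = 10)
  expect_equal(sh$volume, 1, tolerance = 1e-9)
  g <- voxel_grid_spec(c(0, 0, 0), 0.1)
  vx <- voxelize_alpha_shape(sh, g)
  expect_equal(nrow(vx), 1000)

  # empty shape -> empty voxel set
  sh0 <- update_alpha(sh, 1e-6)
  expect_equal(nrow(voxelize_alpha_shape(sh0, g)), 0)
})

test_that("alpha-shape voxelization equals the exhaustive center test on random tetrahedra", {
  set.seed(52)
  g <- voxel_grid_spec(c(0, 0, 0), 0.1)
  for (trial in 1:5) {
    verts <- matrix(runif(12, 0, 1.2), ncol = 3)
    vol <- abs(det(rbind(verts[2, ] - verts[1, ], verts[3, ] - verts[1, ],
                         verts[4, ] - verts[1, ]))) / 6
    if (vol < 1e-4) next
    sh <- structure(list(vertices = verts,
                         tetra = matrix(1:4, nrow = 1),
                         alpha = Inf),
                    class = "alpha_shape_3d")
    got <- voxelize_alpha_shape(sh, g)
    want <- bf_voxelize_tetra(verts, matrix(1:4, nrow = 1), g$origin, 0.1)
    expect_same_voxels(got, want)
  }
})

test_that("crown/stem split partitions by height above ground", {
  dtm <- flat_dtm(0, extent = 3)
  pc <- point_cloud(c(0.5, 0.5), c(0.5, 0.5), c(1.0, 3.0))
  parts <- split_crown_stem(pc, 2.0, dtm)
  expect_equal(npoints(parts$stem), 1)
  expect_equal(npoints(parts$crown), 1)
  expect_equal(parts$crown$z, 3.0)

  # all below cbh -> empty crown
  low <- point_cloud(runif(10), runif(10), runif(10, 0, 0.5))
  expect_equal(npoints(split_crown_stem(low, 2, dtm)$crown), 0)

  # random cloud equals the per-point comparison
  set.seed(61)
  r <- point_cloud(runif(300, 0, 2), runif(300, 0, 2), runif(300, 0, 6))
  pr <- split_crown_stem(r, 2.5, dtm)
  hag <- height_above_ground(dtm, r$x, r$y, r$z)
  expect_equal(npoints(pr$crown), sum(hag >= 2.5))
  expect_equal(npoints(pr$crown) + npoints(pr$stem), 300)
})

test_that("tree model merges alpha and point voxels with crown precedence", {
  dtm <- flat_dtm(0, extent = 3)
  g <- voxel_grid_spec(c(0, 0, 0), 0.1)

  # empty crown, stem points in one voxel -> one stem voxel
  stem <- point_cloud(rep(0.05, 10), rep(0.05, 10), seq(0.2, 0.29, 0.01))
  m0 <- build_tree_model(point_cloud(numeric(0), numeric(0), numeric(0)),
                         stem, g, tree_id = "t", species = "s", year = 1)
  expect_equal(nrow(m0), 1)
  expect_equal(m0$compartment, "stem")

  # crown filling a cube: model is a superset of the direct voxelization
  set.seed(71)
  cm <- matrix(runif(1500, 1, 2), ncol = 3)
  crown <- point_cloud(cm[, 1], cm[, 2], cm[, 3])
  mdl <- build_tree_model(crown, stem, g, alpha = 5, tree_id = "t",
                          species = "s", year = 1)
  direct <- voxelize_points(crown, g)
  joined <- merge(direct, mdl[, .(i, j, k)], by = c("i", "j", "k"))
  expect_equal(nrow(joined), nrow(direct))
  # every direct crown voxel is labeled crown, sources valid
  expect_true(all(mdl$source %in% c("alpha", "points", "both")))

  # fewer than 4 crown points: warning, direct voxelization still applied
  tiny <- point_cloud(1.5, 1.5, 1.5)
  expect_warning(m1 <- build_tree_model(tiny, stem, g, tree_id = "t",
                                        species = "s", year = 1),
                 "alpha shape skipped")
  expect_true(any(m1$compartment == "crown"))

  # stem voxel colliding with a crown voxel keeps the crown label
  stem_hi <- point_cloud(1.55, 1.55, 1.55)
  mc <- build_tree_model(crown, stem_hi, g, alpha = 5, tree_id = "t",
                         species = "s", year = 1)
  hit <- merge(voxelize_points(stem_hi, g), mc, by = c("i", "j", "k"))
  expect_equal(hit$compartment, "crown")
})

test_that("alpha monotonicity carries through to voxel sets", {
  set.seed(81)
  m <- matrix(runif(900, 0, 1.5), ncol = 3)
  pc <- point_cloud(m[, 1], m[, 2], m[, 3])
  g <- voxel_grid_spec(c(0, 0, 0), 0.1)
  sh <- alpha_shape_3d(pc, alpha = 0.25)
  v1 <- voxelize_alpha_shape(sh, g)
  v2 <- voxelize_alpha_shape(update_alpha(sh, 0.6), g)
  joined <- merge(v1, v2, by = c("i", "j", "k"))
  expect_equal(nrow(joined), nrow(v1))   # v1 subset of v2
})

test_that("voxel counts behave sanely under voxel-size doubling", {
  set.seed(91)
  m <- matrix(runif(3000, 0, 2), ncol = 3)
  pc <- point_cloud(m[, 1], m[, 2], m[, 3])
  vol_s <- function(s)
    nrow(voxelize_points(pc, voxel_grid_spec(c(0, 0, 0), s))) * s^3
  # occupied volume changes by at most 8x when the edge doubles
  expect_lt(vol_s(0.2) / vol_s(0.1), 8)
  expect_gt(vol_s(0.2) / vol_s(0.1), 1)
  # below the minimum point spacing every point gets its own voxel
  sparse <- point_cloud(seq(0, 1, 0.1), seq(0, 1, 0.1), seq(0, 1, 0.1))
  expect_equal(nrow(voxelize_points(sparse, voxel_grid_spec(c(0, 0, 0), 0.01))),
               11)
})

test_that("tree model CSV round-trips with grid metadata", {
  g <- voxel_grid_spec(c(0.3, -1, 0), 0.1, 10.3)
  vox <- cbind(c(1, 2, 3), c(0, 0, 1), c(5, 6, 7))
  mdl <- toy_model(vox, g, "T42", "narrow", 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tree_model(mdl, f)
  back <- read_tree_model(f)
  expect_equal(attr(back, "tree_id"), "T42")
  expect_equal(attr(back, "grid")$origin, g$origin)
  expect_equal(back$i, mdl$i)
  expect_equal(back$compartment, mdl$compartment)
})
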