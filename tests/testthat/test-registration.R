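test_that("stem circle fit recovers exact and partial-arc circles", {
  dtm <- flat_dtm(0, extent = 6)
  full <- circle_points(36, 2, 3, 0.04, z = 0.05)
  p <- fit_stem_circle(full, dtm, tree_id = "a", year = 1)
  expect_equal(p$x, 2, tolerance = 1e-9)
  expect_equal(p$y, 3, tolerance = 1e-9)
  expect_equal(p$radius, 0.04, tolerance = 1e-9)
  expect_equal(p$ground_z, 0)

  half <- circle_points(40, 2, 3, 0.04, arc = c(0, pi), z = 0.05)
  ph <- fit_stem_circle(half, dtm)
  expect_equal(ph$x, 2, tolerance = 1e-6)
  expect_equal(ph$y, 3, tolerance = 1e-6)
})

test_that("circle fit is translation-equivariant and rejects degenerate slices", {
  dtm <- flat_dtm(0, extent = 12)
  pc <- circle_points(25, 0, 0, 0.05, arc = c(0.3, 5.1), z = 0.05)
  a <- fit_stem_circle(pc, dtm)
  shifted <- point_cloud(pc$x + 1.7, pc$y - 2.2, pc$z)
  b <- fit_stem_circle(shifted, dtm)
  expect_equal(b$x - a$x, 1.7, tolerance = 1e-9)
  expect_equal(b$y - a$y, -2.2, tolerance = 1e-9)

  expect_error(fit_stem_circle(point_cloud(0, 0, 5), dtm), "no stem slice")
  line <- point_cloud(seq(0, 0.1, length.out = 10), rep(0, 10), rep(0.05, 10))
  expect_error(fit_stem_circle(line, dtm), "degenerate|collinear")
})

test_that("circle center recovery under 2 mm noise is sub-millimetre on average", {
  dtm <- flat_dtm(0, extent = 6)
  set.seed(101)
  errs <- replicate(100, {
    base <- circle_points(200, 1, 1, 0.035, z = 0.05)
    noisy <- point_cloud(base$x + rnorm(200, 0, 0.002),
                         base$y + rnorm(200, 0, 0.002), base$z)
    p <- fit_stem_circle(noisy, dtm)
    sqrt((p$x - 1)^2 + (p$y - 1)^2)
  })
  expect_lt(mean(errs), 0.001)
})

test_that("conformal transform: identity, exact recovery, and noise-scale residuals", {
  set.seed(21)
  ref <- data.frame(tree_id = 1:16, x = runif(16, 0, 5), y = runif(16, 0, 5))
  expect_warning(idt <- estimate_conformal_2d(ref, ref), NA)
  expect_equal(idt$scale, 1, tolerance = 1e-12)
  expect_equal(idt$rotation, 0, tolerance = 1e-12)
  expect_equal(idt$rms_residual, 0, tolerance = 1e-12)

  # known similarity, noiseless: parameters to 1e-9 via the inverse mapping
  for (sc in c(0.99, 1.0)) {
    tf0 <- conformal2d(scale = sc, rotation = 30 * pi / 180, tx = 1, ty = 2)
    inv <- invert_transform(tf0)
    mov <- data.frame(tree_id = ref$tree_id)
    th <- inv$rotation
    mov$x <- inv$scale * (cos(th) * ref$x - sin(th) * ref$y) + inv$tx
    mov$y <- inv$scale * (sin(th) * ref$x + cos(th) * ref$y) + inv$ty
    est <- suppressWarnings(estimate_conformal_2d(ref, mov))
    expect_equal(est$scale, sc, tolerance = 1e-9)
    expect_equal(est$rotation, 30 * pi / 180, tolerance = 1e-9)
    expect_equal(est$tx, 1, tolerance = 1e-8)
    expect_equal(est$ty, 2, tolerance = 1e-8)
    expect_lt(est$rms_residual, 1e-9)
  }

  # 1 cm isotropic noise -> mean matched-pair residual on that order
  set.seed(22)
  res <- replicate(50, {
    mov <- data.frame(tree_id = ref$tree_id,
                      x = ref$x + rnorm(16, 0, 0.01),
                      y = ref$y + rnorm(16, 0, 0.01))
    estimate_conformal_2d(ref, mov)$mean_residual
  })
  expect_gt(mean(res), 0.005)
  expect_lt(mean(res), 0.02)
})

test_that("conformal residual is invariant under a common rigid motion", {
  set.seed(31)
  ref <- data.frame(tree_id = 1:10, x = runif(10, 0, 4), y = runif(10, 0, 4))
  mov <- data.frame(tree_id = 1:10, x = ref$x + rnorm(10, 0, 0.02),
                    y = ref$y + rnorm(10, 0, 0.02))
  base <- estimate_conformal_2d(ref, mov)$rms_residual
  rot <- conformal2d(rotation = 0.7, tx = 3, ty = -2)
  spin <- function(d) {
    xy <- with(d, list(x = cos(0.7) * x - sin(0.7) * y + 3,
                       y = sin(0.7) * x + cos(0.7) * y - 2))
    data.frame(tree_id = d$tree_id, x = xy$x, y = xy$y)
  }
  moved <- estimate_conformal_2d(spin(ref), spin(mov))$rms_residual
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("matching is by tree id; unmatched trees are dropped with a warning", {
  ref <- data.frame(tree_id = c("a", "b", "c"), x = c(0, 1, 0), y = c(0, 0, 1))
  mov <- data.frame(tree_id = c("a", "b", "d"), x = c(0, 1, 9), y = c(0, 0, 9))
  expect_warning(tf <- estimate_conformal_2d(ref, mov), "dropped")
  expect_equal(tf$n, 2)
  expect_error(estimate_conformal_2d(ref[1, ], mov[1, ]), "at least 2")
})

test_that("height leveling equals the difference of mean ground levels", {
  a <- data.frame(ground_z = c(1, 2, 3))
  b <- data.frame(ground_z = c(1, 2, 3))
  expect_equal(align_heights(a, b), 0)
  b2 <- data.frame(ground_z = c(1, 2, 3) - 0.25)
  expect_equal(align_heights(a, b2), 0.25)
  set.seed(4)
  r1 <- data.frame(ground_z = rnorm(9)); r2 <- data.frame(ground_z = rnorm(7))
  expect_equal(align_heights(r1, r2), mean(r1$ground_z) - mean(r2$ground_z))
  tf <- align_heights(r1, r2, conformal2d())
  expect_equal(tf$dz, mean(r1$ground_z) - mean(r2$ground_z))
  expect_error(align_heights(data.frame(ground_z = numeric(0)), r2), "empty")
})

test_that("apply_transform maps points as documented and composes with its inverse", {
  pc <- point_cloud(0, 0, 0)
  t1 <- conformal2d(tx = 1)
  expect_equal(as.numeric(apply_transform(pc, t1)[1, 1:3]), c(1, 0, 0))
  idp <- apply_transform(pc, conformal2d())
  expect_equal(as.data.frame(idp), as.data.frame(pc))

  set.seed(12)
  cloud <- point_cloud(runif(50), runif(50), runif(50), intensity = 1:50)
  tf <- conformal2d(scale = 1.01, rotation = 0.4, tx = -2, ty = 5, dz = 0.3)
  back <- apply_transform(apply_transform(cloud, tf), invert_transform(tf))
  expect_equal(back$x, cloud$x, tolerance = 1e-9)
  expect_equal(back$y, cloud$y, tolerance = 1e-9)
  expect_equal(back$z, cloud$z, tolerance = 1e-9)
  expect_equal(back$intensity, cloud$intensity)
})

test_that("transforms serialize to JSON and back", {
  tf <- conformal2d(scale = 1.002, rotation = 0.3, tx = 1.5, ty = -0.7,
                    dz = 0.12)
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f)
  back <- read_transform(f)
  expect_equal(back$scale, tf$scale)
  expect_equal(back$rotation, tf$rotation)
  expect_equal(back$dz, tf$dz)
})
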