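# shared toy setting: flat ground at 0, 10 cm voxels, area [0,2) x [0,2) x 3 m
toy_setting <- function() {
  dtm <- flat_dtm(0, extent = 8)
  grid <- voxel_grid_spec(c(-8, -8, -1), 0.1, 10.3)
  area <- investigation_area(c(0, 2), c(0, 2), height = 3)
  list(dtm = dtm, grid = grid, area = area)
}

# a column-aligned block of voxels: i in i0..i1 etc (above ground: k >= 10)
block <- function(i, j, k) as.matrix(expand.grid(i = i, j = j, k = k))

test_that("occupancy table records one row per voxel-tree-year and counts folds", {
  s <- toy_setting()
  m1 <- toy_model(block(85:86, 85, 15), s$grid, "A", "broad", 1)
  m2 <- toy_model(block(85, 85, 15), s$grid, "B", "narrow", 1)
  tab <- build_occupancy_table(list(m1, m2), s$dtm, s$grid)
  expect_equal(nrow(tab), 3)
  expect_equal(nrow(unique(tab[, .(i, j, k, tree_id, year)])), nrow(tab))
  occ <- tab[, .N, by = .(i, j, k)]
  expect_equal(sort(occ$N), c(1, 2))

  # height above ground equals center z minus the flat ground
  expect_equal(tab$height_above_ground,
               tab$z_center, tolerance = 1e-12)

  # voxels above the cap are excluded
  high <- toy_model(block(85, 85, 200), s$grid, "C", "broad", 1)
  tab2 <- build_occupancy_table(list(m1, high), s$dtm, s$grid)
  expect_false("C" %in% tab2$tree_id)

  # mixed grids are rejected
  g2 <- voxel_grid_spec(c(0, 0, 0), 0.1)
  m3 <- toy_model(block(1, 1, 1), g2, "D", "broad", 1)
  expect_error(build_occupancy_table(list(m1, m3), s$dtm, s$grid),
               "same voxel grid")
})

test_that("occupancy equals the brute-force count over random overlapping models", {
  s <- toy_setting()
  set.seed(33)
  models <- lapply(1:5, function(t) {
    vox <- block(sample(80:92, 6), sample(80:92, 6), sample(12:25, 4))
    toy_model(unique(vox), s$grid, paste0("T", t),
              sample(c("broad", "narrow"), 1), 1)
  })
  tab <- build_occupancy_table(models, s$dtm, s$grid)
  occ <- tab[, .(n = data.table::uniqueN(tree_id)), by = .(i, j, k)]
  for (r in sample(nrow(occ), 20)) {
    n_bf <- sum(vapply(models, function(m)
      any(m$i == occ$i[r] & m$j == occ$j[r] & m$k == occ$k[r]), TRUE))
    expect_equal(occ$n[r], n_bf)
  }
})

test_that("crown volume counts crown voxels times the voxel volume", {
  s <- toy_setting()
  one <- toy_model(block(85, 85, 15), s$grid, "A", "broad", 1)
  kilo <- toy_model(block(80:89, 80:89, 10:19), s$grid, "B", "narrow", 1)
  stem_only <- toy_model(block(70, 70, 10:12), s$grid, "C", "broad", 1,
                         compartment = "stem")
  tab <- build_occupancy_table(list(one, kilo, stem_only), s$dtm, s$grid)
  expect_equal(crown_volume(tab, "A", 1), 0.001)
  expect_equal(crown_volume(tab, "B", 1), 1.0)
  expect_equal(crown_volume(tab, "C", 1), 0)   # stem voxels are not crown
  expect_error(crown_volume(tab, "Z", 1), "unknown")
})

test_that("crown intersection volume splits intra/inter and is symmetric for pairs", {
  s <- toy_setting()
  # two identical single-species crowns: civ_total = CV, all intraspecific
  a <- toy_model(block(85:86, 85, 15), s$grid, "A", "broad", 1)
  b <- toy_model(block(85:86, 85, 15), s$grid, "B", "broad", 1)
  tab <- build_occupancy_table(list(a, b), s$dtm, s$grid)
  va <- crown_intersection_volume(tab, "A", 1)
  vb <- crown_intersection_volume(tab, "B", 1)
  expect_equal(va$civ_total, crown_volume(tab, "A", 1))
  expect_equal(va$civ_total, vb$civ_total)
  expect_equal(va$civ_intra, va$civ_total)
  expect_equal(va$civ_inter, 0)

  # disjoint crowns: zero
  c2 <- toy_model(block(50, 50, 15), s$grid, "C", "broad", 1)
  tab2 <- build_occupancy_table(list(a, c2), s$dtm, s$grid)
  expect_equal(crown_intersection_volume(tab2, "A", 1)$civ_total, 0)

  # 3-tree pattern with known sets, mixed species
  #  A: voxels 1..4 ; B (broad): voxels 3..6 ; C (narrow): voxels 4..8
  mkA <- toy_model(block(81:84, 85, 15), s$grid, "A", "broad", 1)
  mkB <- toy_model(block(83:86, 85, 15), s$grid, "B", "broad", 1)
  mkC <- toy_model(block(84:88, 85, 15), s$grid, "C", "narrow", 1)
  t3 <- build_occupancy_table(list(mkA, mkB, mkC), s$dtm, s$grid)
  vA <- crown_intersection_volume(t3, "A", 1)
  # A shares 83 (with B) and 84 (with B and C)
  expect_equal(vA$civ_total, 2 * 0.001)
  expect_equal(vA$civ_intra, 2 * 0.001)   # both shared voxels have broad B
  expect_equal(vA$civ_inter, 1 * 0.001)   # only 84 has narrow C
  expect_equal(vA$by_fold[fold_class == "2", volume_m3], 0.001)
  expect_equal(vA$by_fold[fold_class == "3", volume_m3], 0.001)
})

test_that("investigation area: analytic volume and clipping rules", {
  area <- investigation_area(c(0, 6), c(0, 6), height = 10.3)
  expect_equal(area_volume(area), 370.8)

  s <- toy_setting()
  # voxel centered at 10.35 m above ground exceeds the 10.3 m cap and never
  # enters the table; one at 10.25 m stays but is clipped by a lower limit
  hi <- toy_model(block(100, 100, c(112, 113)), s$grid, "H", "broad", 1)
  tabh <- build_occupancy_table(list(hi), s$dtm, s$grid)
  expect_equal(tabh$height_above_ground, 10.25)
  area_low <- investigation_area(c(2, 3), c(2, 3), height = 10.2)
  expect_warning(cl <- clip_investigation_area(tabh, area_low), "no records")
  expect_equal(nrow(cl), 0)

  # brute-force filter equivalence on a random table
  set.seed(55)
  models <- lapply(1:4, function(t)
    toy_model(unique(block(sample(70:100, 8), sample(70:100, 8),
                           sample(10:40, 5))), s$grid, paste0("T", t),
              "broad", 1))
  tab <- build_occupancy_table(models, s$dtm, s$grid)
  clp <- clip_investigation_area(tab, s$area)
  bf <- tab[x_center >= 0 & x_center < 2 & y_center >= 0 & y_center < 2 &
              height_above_ground >= 0 & height_above_ground <= 3]
  expect_equal(nrow(clp), nrow(bf))
  expect_equal(sort(paste(clp$i, clp$j, clp$k, clp$tree_id)),
               sort(paste(bf$i, bf$j, bf$k, bf$tree_id)))
})

test_that("occupancy volumes: per-voxel single counting and exact conservation", {
  s <- toy_setting()
  # single one-voxel tree
  one <- toy_model(block(85, 85, 15), s$grid, "A", "broad", 1)
  tab1 <- build_occupancy_table(list(one), s$dtm, s$grid)
  ov1 <- occupancy_volumes(tab1, s$area, 1)
  expect_equal(ov1[class == "1", volume_m3], 0.001)
  expect_equal(sum(ov1[class %in% c("2", "3", "4+"), volume_m3]), 0)

  # two fully overlapping 100-voxel crowns: twofold 0.1, single 0
  ca <- toy_model(block(81:90, 81:90, 15), s$grid, "A", "broad", 1)
  cb <- toy_model(block(81:90, 81:90, 15), s$grid, "B", "narrow", 1)
  tab2 <- build_occupancy_table(list(ca, cb), s$dtm, s$grid)
  ov2 <- occupancy_volumes(tab2, s$area, 1)
  expect_equal(ov2[class == "2", volume_m3], 0.1)
  expect_equal(ov2[class == "1", volume_m3], 0)

  # conservation: classes sum to the region's voxel budget, exactly
  budget <- region_voxel_budget(s$area, s$grid, s$dtm)
  expect_equal(sum(ov2$n_voxels), budget)
  expect_equal(sum(ov2$volume_m3), budget * 0.001)

  # flat ground, aligned 6 x 6 x 10.3 area: budget matches the analytic
  # volume at 10 cm voxels (60 x 60 x 103 voxels = 370.8 m^3)
  area6 <- investigation_area(c(-6, 0), c(-6, 0), height = 10.3)
  expect_equal(region_voxel_budget(area6, s$grid, s$dtm) * 0.001, 370.8)
})

test_that("layer aggregation partitions the area totals", {
  s <- toy_setting()
  set.seed(66)
  models <- lapply(1:3, function(t)
    toy_model(unique(block(sample(80:99, 10), sample(80:99, 10),
                           sample(11:38, 8))), s$grid, paste0("T", t),
              c("broad", "narrow")[1 + t %% 2], 1))
  tab <- build_occupancy_table(models, s$dtm, s$grid)
  whole <- occupancy_volumes(tab, s$area, 1)
  lay <- layer_aggregate(tab, s$area,
                         data.frame(name = c("low", "high"),
                                    z_low = c(0, 1.5), z_high = c(1.5, 3.5)),
                         1)
  for (cl in c("1", "2", "3", "4+", "empty")) {
    expect_equal(sum(lay[class == cl, volume_m3]),
                 whole[class == cl, volume_m3])
  }
  # full-height layer equals the unrestricted result
  full <- layer_aggregate(tab, s$area,
                          data.frame(name = "all", z_low = 0, z_high = 99), 1)
  expect_equal(full$volume_m3, whole$volume_m3)
  # empty layer above all crowns
  top <- layer_aggregate(tab, s$area,
                         data.frame(name = "top", z_low = 2.9, z_high = 3.0),
                         1)
  expect_equal(sum(top[class != "empty", n_voxels]), 0)
  expect_warning(layer_aggregate(tab, s$area,
                                 data.frame(name = c("a", "b"),
                                            z_low = c(0, 1), z_high = c(2, 3)),
                                 1),
                 "overlap")
})

test_that("change detection categorizes per-voxel differences and is antisymmetric", {
  s <- toy_setting()
  a1 <- toy_model(block(85:88, 85, 15), s$grid, "A", "broad", 1)
  b1 <- toy_model(block(86, 85, 15), s$grid, "B", "narrow", 1)
  a2 <- toy_model(block(85:88, 85, 15), s$grid, "A", "broad", 2)
  b2 <- toy_model(block(86:89, 85, 15), s$grid, "B", "narrow", 2)
  tab <- build_occupancy_table(list(a1, b1, a2, b2), s$dtm, s$grid)

  cm <- change_detection(tab, 1, 2, s$area)
  # i 85: 1 -> 1, i 86: 2 -> 2 (unchanged); i 87, 88: 1 -> 2 and i 89:
  # 0 -> 1 (increased)
  summ <- attr(cm, "summary")
  expect_equal(summ[category == "increased", n], 3L)
  expect_equal(summ[category == "decreased", n], 0L)
  expect_equal(summ[category == "unchanged", n], 2L)
  expect_equal(sum(summ$pct), 100)

  # identical years: all unchanged
  cid <- change_detection(tab, 1, 1, s$area)
  expect_equal(attr(cid, "summary")[category == "unchanged", pct], 100)

  # antisymmetry under year swap
  rev <- change_detection(tab, 2, 1, s$area)
  sr <- attr(rev, "summary")
  expect_equal(sr[category == "decreased", n],
               summ[category == "increased", n])
  expect_equal(sr[category == "increased", n],
               summ[category == "decreased", n])
  expect_equal(sr[category == "unchanged", n],
               summ[category == "unchanged", n])

  # brute-force per-voxel delta on a random pair
  set.seed(77)
  m1 <- lapply(1:3, function(t)
    toy_model(unique(block(sample(80:99, 7), sample(80:99, 7),
                           sample(11:25, 4))), s$grid, paste0("T", t),
              "broad", 1))
  m2 <- lapply(1:3, function(t)
    toy_model(unique(block(sample(80:99, 7), sample(80:99, 7),
                           sample(11:25, 4))), s$grid, paste0("T", t),
              "broad", 2))
  tt <- build_occupancy_table(c(m1, m2), s$dtm, s$grid)
  cmr <- change_detection(tt, 1, 2, s$area)
  clp <- clip_investigation_area(tt, s$area)
  for (r in sample(nrow(cmr), min(15, nrow(cmr)))) {
    o1 <- clp[year == 1 & i == cmr$i[r] & j == cmr$j[r] & k == cmr$k[r],
              data.table::uniqueN(tree_id)]
    o2 <- clp[year == 2 & i == cmr$i[r] & j == cmr$j[r] & k == cmr$k[r],
              data.table::uniqueN(tree_id)]
    expect_equal(cmr$delta[r], o2 - o1)
  }

  # include_empty evaluates the full region budget
  cme <- change_detection(tt, 1, 2, s$area, include_empty = TRUE)
  expect_equal(nrow(cme), region_voxel_budget(s$area, s$grid, s$dtm))
})

test_that("heat maps export column counts whose total matches the table", {
  s <- toy_setting()
  a <- toy_model(block(82:85, 83, 15:17), s$grid, "A", "broad", 1)
  b <- toy_model(block(84, 83, 15), s$grid, "B", "narrow", 1)
  tab <- build_occupancy_table(list(a, b), s$dtm, s$grid)
  f <- withr::local_tempfile(fileext = ".csv")
  m <- heatmap_export(tab, f, s$area, year = 1)
  expect_true(file.exists(f))
  clp <- clip_investigation_area(tab, s$area)
  expect_equal(sum(m), nrow(clp[compartment == "crown"]))
  expect_equal(sum(m > 0), 4)        # four occupied columns
  expect_equal(max(m), 4)            # 3 voxels of A + the shared B record

  # all-empty layer: zero matrix
  m0 <- heatmap_export(tab, f, s$area, year = 1, z_lo = 2.5, z_hi = 2.9)
  expect_true(all(m0 == 0))
})
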