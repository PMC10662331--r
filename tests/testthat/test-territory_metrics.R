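test_that("area occupancy is the union share of the nucleus", {
  nuc <- matrix(FALSE, 50, 50); nuc[6:45, 6:30] <- TRUE  # 1000 px
  t1 <- matrix(FALSE, 50, 50); t1[10:18, 10:16] <- TRUE  # 63 px
  expect_equal(area_occupancy(list(t1), nuc), 63 / 1000)
  expect_equal(area_occupancy(list(), nuc), 0)
  expect_equal(area_occupancy(list(nuc), nuc), 1)
  # overlapping territories count each pixel once
  t2 <- matrix(FALSE, 50, 50); t2[14:22, 10:16] <- TRUE
  both <- sum((t1 | t2) & nuc)
  expect_equal(area_occupancy(list(t1, t2), nuc), both / 1000)
})

test_that("density ratios recover constructed median contrasts", {
  nuc <- matrix(FALSE, 60, 60); nuc[6:55, 6:55] <- TRUE
  ter <- matrix(FALSE, 60, 60); ter[10:24, 10:24] <- TRUE
  dapi <- matrix(0, 60, 60); dapi[nuc] <- 100; dapi[ter] <- 200
  expect_equal(density_ratio(dapi, ter, nuc)$r_fragment, 2)
  uni <- matrix(137, 60, 60)
  expect_equal(density_ratio(uni, ter, nuc)$r_fragment, 1)
  # invariance to positive rescaling
  expect_equal(density_ratio(dapi * 3.7, ter, nuc)$r_fragment, 2)
  expect_error(density_ratio(matrix(0, 60, 60), ter, nuc), "zero nuclear")
})

test_that("axial angles follow displacement relative to the major axis", {
  shp <- nucleus_morphometry(make_ellipse_mask(160, 200, 100, 80, 70, 40, 0),
                             0.1)
  ctr <- c(shp$centroid_x, shp$centroid_y)
  along <- axial_angle(ctr + c(30, 0), ctr, shp$orientation_deg)
  expect_equal(along$theta_deg, 0, tolerance = 0.5)
  expect_equal(along$axial_class, "major_parallel")
  up <- axial_angle(ctr + c(0, -25), ctr, shp$orientation_deg)
  expect_equal(up$theta_deg, 90, tolerance = 0.5)
  expect_equal(up$axial_class, "minor_parallel")
  coincident <- axial_angle(ctr, ctr, shp$orientation_deg)
  expect_true(coincident$undefined_angle)
})

test_that("axial angle is invariant to rigid rotation of the scene", {
  for (rot in c(0, 30, 75, 120)) {
    m <- make_ellipse_mask(220, 220, 110, 110, 80, 45, rot)
    shp <- nucleus_morphometry(m, 0.1)
    # territory displaced 25 degrees from the major axis, co-rotated
    ang <- (rot + 25) * pi / 180
    cen <- c(shp$centroid_x + 40 * cos(ang),
             shp$centroid_y - 40 * sin(ang))
    th <- axial_angle(cen, c(shp$centroid_x, shp$centroid_y),
                      shp$orientation_deg)$theta_deg
    th_fold <- min(th, 180 - th)
    expect_equal(th_fold, 25, tolerance = 0.5)
  }
})

test_that("the 45/135-degree rule classifies boundaries as major-parallel", {
  expect_equal(classify_axial(45), "major_parallel")
  expect_equal(classify_axial(135), "major_parallel")
  expect_equal(classify_axial(44.999), "major_parallel")
  expect_equal(classify_axial(45.001), "minor_parallel")
  expect_equal(classify_axial(90), "minor_parallel")
})

test_that("per-cell classes follow the scheme rules", {
  mm <- c("minor_parallel", "minor_parallel")
  expect_equal(classify_cell(mm, "normal")$cell_axial_class, "both_minor")
  expect_equal(classify_cell(c("major_parallel", "minor_parallel"),
                             "normal")$cell_axial_class, "one_plus_major")
  expect_equal(classify_cell(rep(c("major_parallel", "minor_parallel"),
                                 each = 2), "tumor")$cell_axial_class,
               ">=50%_major")
  expect_equal(classify_cell(c("major_parallel", rep("minor_parallel", 3)),
                             "tumor")$cell_axial_class, "<50%_major")
  expect_error(classify_cell(c("minor_parallel"), "normal"),
               "exactly 2")
})

test_that("normal and tumor schemes agree on two-territory cells", {
  cls <- c("major_parallel", "minor_parallel")
  for (a in cls) for (b in cls) {
    norm <- classify_cell(c(a, b), "normal")$cell_axial_class
    tum <- classify_cell(c(a, b), "tumor")$cell_axial_class
    # both_minor coincides with <50%_major exactly
    expect_equal(norm == "both_minor", tum == "<50%_major")
  }
})

test_that("inter-territory geometry follows plane geometry", {
  expect_equal(inter_territory_distance(c(0, 0), c(3, 4), 1), 5)
  expect_equal(inter_territory_distance(c(2, 2), c(2, 2), 1), 0)
  expect_equal(inter_territory_distance(c(0, 0), c(3, 4), 0.5), 2.5)
  ctr <- c(10, 10)
  expect_equal(inter_territory_angle(c(15, 10), c(5, 10), ctr)$angle_deg, 180)
  expect_equal(inter_territory_angle(c(15, 10), c(20, 10), ctr)$angle_deg, 0)
  expect_equal(inter_territory_angle(c(15, 10), c(10, 4), ctr)$angle_deg, 90)
  expect_true(inter_territory_angle(ctr, c(5, 5), ctr)$undefined_angle)
})
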