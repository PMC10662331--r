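test_that("a zero-exponent gradient renders uniform DAPI inside the mask", {
  ns <- nucleus_spec(c(40, 35), 25, 16, 50, dapi_gradient_exponent = 0)
  nuc <- generate_nucleus(ns, c(70, 80))
  vals <- nuc$dapi[nuc$mask]
  expect_true(all(vals == vals[1]))
  expect_true(all(nuc$dapi[!nuc$mask] == 0))
})

test_that("generated 2:1 ellipses measure the closed-form eccentricity", {
  ns <- nucleus_spec(c(80, 70), 50, 25, 110)
  nuc <- generate_nucleus(ns, c(140, 160))
  s <- nucleus_morphometry(nuc$mask, 0.1)
  expect_equal(s$eccentricity, sqrt(3) / 2, tolerance = 0.02)
  expect_equal(s$orientation_deg, 110, tolerance = 1)
})

test_that("rendered DAPI equals the analytic gradient when noiseless", {
  sc <- demo_scene(seed = 31, noise = 0, dapi_contrast = 1, exponent = 1,
                   bg_gradient = 0)
  msk <- sc$nucleus_labels > 0
  ring <- ring_partition(msk, 6)
  rho <- attr(ring, "rho")
  expected <- round(150 + 90 * rho[msk])
  expect_equal(sc$dapi$pixels[msk], expected)
})

test_that("scene generation is deterministic given the seed", {
  s1 <- demo_scene(seed = 21, noise = 8)
  s2 <- demo_scene(seed = 21, noise = 8)
  expect_identical(s1$dapi$pixels, s2$dapi$pixels)
  expect_identical(s1$paint$pixels, s2$paint$pixels)
  expect_identical(s1$truth, s2$truth)
  s3 <- demo_scene(seed = 22, noise = 8)
  expect_false(identical(s1$dapi$pixels, s3$dapi$pixels))
})

test_that("territory counts match truth rows and connected components", {
  sc <- demo_scene(seed = 23, n_territories = 2L)
  expect_equal(nrow(sc$truth), 2L)
  lab <- EBImage::bwlabel(t(sc$territory_labels > 0))
  expect_equal(max(lab), 2)
})

test_that("ellipses exceeding the frame are rejected", {
  ns <- nucleus_spec(c(20, 20), 30, 20)
  expect_error(generate_nucleus(ns, c(60, 60)), "exceeds")
  expect_error(nucleus_spec(c(10, 10), 5, 9), "semi_minor")
})

test_that("extreme angular concentration places all territories major-parallel", {
  sc <- demo_scene(seed = 25, kappa = 1e5)
  expect_true(all(classify_axial(sc$truth$theta_sampled_deg) ==
                    "major_parallel"))
})

test_that("with a positive gradient the measured ring DAPI means rise
           outward, as in peripheral heterochromatin staining", {
  sc <- demo_scene(seed = 26, noise = 8, exponent = 1)
  seg <- segment_nuclei(sc$dapi)
  ring <- ring_partition(seg$labels == 1L, 6)
  dp <- dapi_ring_intensity(sc$dapi$pixels, ring)
  expect_true(all(diff(dp$mean_intensity) > 0))
})

test_that("cohorts reproduce bit-identical truth under one master seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cohort <- list(
    grpA = list(n_scenes = 2L, nuclei_per_scene = 2L,
                nucleus_params = list(major_um = 10, minor_um = 7),
                placement = placement_spec(n_territories = 2L,
                                           territory_area_fraction = 0.06)))
  r1 <- generate_cohort(cohort, d1, seed = 99)
  r2 <- generate_cohort(cohort, d2, seed = 99)
  t1 <- r1$truth[setdiff(names(r1$truth), "path")]
  t2 <- r2$truth[setdiff(names(r2$truth), "path")]
  expect_identical(t1, t2)
  expect_equal(nrow(r1$nucleus_truth), 4L)       # one row per nucleus
  expect_equal(nrow(r1$truth), 8L)               # two territories each
  # the scene files themselves are identical
  expect_identical(readBin(r1$paths[1], "raw", 2e6),
                   readBin(r2$paths[1], "raw", 2e6))
})

test_that("radial placement follows the requested law", {
  # fixed radial position: achieved rho stays near the sampled target
  ns <- nucleus_spec(c(90, 80), 60, 40, 15)
  ps <- placement_spec(n_territories = 1L,
                       radial_law = list(family = "fixed", value = 0.9),
                       territory_area_fraction = 0.03)
  set.seed(5)
  reps <- replicate(20, {
    nuc <- generate_nucleus(ns, c(160, 180))
    place_territories(nuc, ns, ps)$truth$rho_achieved
  })
  expect_true(all(abs(reps - 0.9) < 0.05))
})
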