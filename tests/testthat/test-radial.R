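test_that("rings partition the mask exactly", {
  for (msk in list(make_ellipse_mask(90, 120, 60, 45, 45, 28, 25),
                   make_ellipse_mask(80, 80, 40, 40, 30, 30))) {
    ring <- ring_partition(msk, 6)
    expect_true(all(ring[msk] >= 1L & ring[msk] <= 6L))
    expect_true(all(ring[!msk] == 0L))
    expect_equal(sum(ring > 0), sum(msk))
    # union of ring areas equals the mask area, each pixel exactly once
    expect_equal(sum(tabulate(ring[ring > 0], 6)), sum(msk))
  }
})

test_that("disc rings put the centre in ring 1 and the boundary in ring 6", {
  msk <- make_ellipse_mask(81, 81, 41, 41, 30, 30)
  ring <- ring_partition(msk, 6)
  expect_equal(ring[41, 41], 1L)
  # boundary pixels: mask pixels adjacent to background
  er <- msk
  er[2:80, 2:80] <- msk[2:80, 2:80] & msk[1:79, 2:80] & msk[3:81, 2:80] &
    msk[2:80, 1:79] & msk[2:80, 3:81]
  boundary <- msk & !er
  expect_true(all(ring[boundary] == 6L))
})

test_that("a single ring collects every pixel", {
  msk <- make_ellipse_mask(40, 40, 20, 20, 12, 9)
  ring <- ring_partition(msk, 1)
  expect_true(all(ring[msk] == 1L))
  expect_error(ring_partition(msk, 0), "n_rings")
})

test_that("uniform paint yields fractions equal to ring area shares", {
  msk <- make_ellipse_mask(100, 130, 65, 50, 50, 32, 10)
  ring <- ring_partition(msk, 6)
  paint <- matrix(3, 100, 130)
  prof <- signal_ring_fractions(paint, ring)
  areas <- tabulate(ring[ring > 0], 6)
  expect_equal(prof$fraction, areas / sum(areas), tolerance = 1e-12)
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
})

test_that("signal confined to one ring gives a one-hot profile", {
  msk <- make_ellipse_mask(100, 100, 50, 50, 40, 40)
  ring <- ring_partition(msk, 6)
  paint <- matrix(0, 100, 100)
  paint[ring == 6L] <- 80
  prof <- signal_ring_fractions(paint, ring)
  expect_equal(prof$fraction, c(0, 0, 0, 0, 0, 1))
})

test_that("profiles are invariant to positive rescaling of the paint", {
  sc <- demo_scene(seed = 12)
  ring <- ring_partition(sc$nucleus_labels > 0, 6)
  p1 <- signal_ring_fractions(sc$paint$pixels, ring)
  p2 <- signal_ring_fractions(sc$paint$pixels * 7.3, ring)
  expect_equal(p1$fraction, p2$fraction, tolerance = 1e-9)
})

test_that("zero paint flags the profile undefined", {
  msk <- make_ellipse_mask(50, 50, 25, 25, 18, 14)
  ring <- ring_partition(msk, 6)
  prof <- signal_ring_fractions(matrix(0, 50, 50), ring)
  expect_true(attr(prof, "undefined"))
  expect_true(all(is.na(prof$fraction)))
})

test_that("DAPI ring means are flat for uniform DAPI, rising for a gradient", {
  msk <- make_ellipse_mask(110, 140, 70, 55, 55, 35, 40)
  ring <- ring_partition(msk, 6)
  flat <- dapi_ring_intensity(matrix(200, 110, 140), ring)
  expect_equal(flat$mean_intensity, rep(200, 6))
  expect_equal(flat$norm_intensity, rep(1, 6))

  # analytic linear-in-rho gradient sampled on the same rho field
  rho <- attr(ring, "rho")
  grad <- matrix(0, 110, 140)
  grad[msk] <- 100 + 150 * rho[msk]
  dp <- dapi_ring_intensity(grad, ring)
  expect_true(all(diff(dp$mean_intensity) > 0))
})

test_that("tiny masks flag a degenerate partition", {
  msk <- matrix(FALSE, 20, 20); msk[10, 9:11] <- TRUE
  ring <- ring_partition(msk, 6)
  dp <- dapi_ring_intensity(matrix(1, 20, 20), ring)
  expect_true(attr(dp, "degenerate"))
})
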