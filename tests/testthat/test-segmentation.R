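test_that("component filters apply the size and border predicates exactly", {
  lab <- matrix(0L, 220, 320)
  lab[5:13, 10:20] <- 1L          # 9 x 11 = 99 px
  lab[30:39, 10:19] <- 2L         # 10 x 10 = 100 px
  lab[60:159, 30:129] <- 3L       # 100 x 100 = 10,000 px
  lab[60:159, 150:249] <- 4L      # 10,000 px ...
  lab[160, 150] <- 4L             # ... + 1 = 10,001 px
  lab[1, 300:310] <- 5L           # touches the frame edge
  info <- filter_components(lab, min_area = 100, max_area = 10000,
                            exclude_border = TRUE)
  info <- info[order(info$label), ]
  expect_equal(info$area_px, c(99L, 100L, 10000L, 10001L, 11L))
  expect_equal(info$retained, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(info$reason[1], "too_small")
  expect_equal(info$reason[4], "too_large")
  expect_true(info$touches_border[5])
})

test_that("a clean ellipse on dark background segments to one accurate mask", {
  # uniform nucleus, no noise: the two-level histogram thresholds exactly
  ns <- nucleus_spec(center = c(70, 60), semi_major_px = 42,
                     semi_minor_px = 30, orientation_deg = 20,
                     dapi_gradient_exponent = 0)
  sc <- generate_scene(list(ns), list(placement_spec(n_territories = 0L)),
                       c(120, 140), noise_sigma = 0, seed = 1)
  seg <- segment_nuclei(sc$dapi)
  expect_equal(sum(seg$info$retained), 1L)
  m <- seg$labels == 1
  truth <- sc$nucleus_labels > 0
  iou <- sum(m & truth) / sum(m | truth)
  expect_gte(iou, 0.95)
})

test_that("nuclei touching the frame or oversized are excluded", {
  h <- 150; w <- 170
  render <- function(masks, seed) {
    xm <- matrix(rep(seq_len(w), each = h), h, w)
    img <- 30 * (1 + 0.15 * (xm / w - 0.5))
    for (m in masks) img[m] <- 180
    set.seed(seed)
    round(pmax(img + rnorm(h * w, 0, 12 * sqrt(img / 100)), 0))
  }
  # one clean nucleus + one cut off by the top frame edge
  inner <- make_ellipse_mask(h, w, 115, 100, 42, 30, 20)
  border <- make_ellipse_mask(h, w, 40, 1, 40, 28, 0)
  seg <- segment_nuclei(channel_image(render(list(inner, border), 2),
                                      0.12, "dapi"))
  border_rows <- seg$info[seg$info$touches_border, ]
  expect_gt(nrow(border_rows), 0)
  expect_true(all(!border_rows$retained))
  expect_true(any(border_rows$reason == "touches_border"))
  expect_equal(sum(seg$info$retained), 1L)

  # ellipse of ~10,500 px is excluded as too large
  big_e <- make_ellipse_mask(h, w, 85, 75, 70, 48, 0)
  expect_gt(sum(big_e), 10000)
  seg3 <- segment_nuclei(channel_image(render(list(big_e), 3),
                                       0.12, "dapi"))
  big <- seg3$info[seg3$info$area_px > 10000, ]
  expect_gt(nrow(big), 0)
  expect_true(all(!big$retained))
  expect_true(all(big$reason == "too_large"))
})

test_that("territory segmentation keeps areas in [100, 10000] only and
           recovers a clean 3x-contrast blob accurately", {
  # noiseless flat-field scene with one ~500-px territory at 3x background
  sc <- demo_scene(seed = 4, noise = 0, bg_gradient = 0, n_territories = 1L,
                   area_fraction = 0.085)
  nuc <- segment_nuclei(sc$dapi)
  paint <- sc$paint$pixels
  # add a 49-px bright speck inside the nucleus: must be excluded by area
  ctr <- which(sc$nucleus_labels > 0 & sc$territory_labels == 0,
               arr.ind = TRUE)
  spot <- ctr[which.min(abs(ctr[, 1] - 20) + abs(ctr[, 2] - 20)), ]
  paint2 <- paint
  paint2[(spot[1] - 3):(spot[1] + 3), (spot[2] - 3):(spot[2] + 3)] <-
    3 * paint2[(spot[1] - 3):(spot[1] + 3), (spot[2] - 3):(spot[2] + 3)]
  ter <- segment_territories(channel_image(paint2, 0.12, "paint"), nuc)
  small <- ter$info[ter$info$area_px < 100, ]
  expect_gt(nrow(small), 0)
  expect_true(all(!small$retained))
  kept <- ter$info[ter$info$retained, ]
  expect_equal(nrow(kept), 1L)
  expect_true(all(kept$area_px >= 100 & kept$area_px <= 10000))
  m <- ter$labels == 1
  truth <- sc$territory_labels == 1
  expect_gte(sum(m & truth) / sum(m | truth), 0.9)
})

test_that("noisy territories are recovered with bounded boundary error", {
  ious <- vapply(1:6, function(s) {
    sc <- demo_scene(seed = s, n_territories = 1L, area_fraction = 0.085)
    nuc <- segment_nuclei(sc$dapi)
    ter <- segment_territories(sc$paint, nuc)
    asg <- assign_to_nuclei(ter, nuc)
    ids <- asg$territory[!is.na(asg$parent_nucleus)]
    best <- 0
    for (id in ids) {
      m <- ter$labels == id
      truth <- sc$territory_labels == 1
      best <- max(best, sum(m & truth) / sum(m | truth))
    }
    best
  }, numeric(1))
  # the max-entropy threshold sits near the background tail, so noisy
  # masks carry a sub-pixel halo; the territory must still dominate
  expect_gte(median(ious), 0.85)
  expect_true(all(ious >= 0.75))
})

test_that("uniform paint propagates a degenerate-histogram error", {
  sc <- demo_scene(seed = 5)
  nuc <- segment_nuclei(sc$dapi)
  flat <- channel_image(matrix(42, 150, 170), 0.12, "paint")
  expect_error(segment_territories(flat, nuc), "degenerate")
})

test_that("segmentation is deterministic", {
  sc <- demo_scene(seed = 6)
  s1 <- segment_nuclei(sc$dapi)
  s2 <- segment_nuclei(sc$dapi)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$threshold, s2$threshold)
})

test_that("territories attach to nuclei by centroid, majority, or not at all", {
  nl <- matrix(0L, 60, 90)
  nl[10:50, 5:40] <- 1L             # nucleus A, convex
  nl[10:50, 50:85] <- 2L            # nucleus B ...
  nl[10:40, 60:75] <- 0L            # ... with a notch (U shape)
  nuc <- structure(list(labels = nl), class = "ct_segmentation")

  # territory 1: centroid plainly inside A
  tl <- matrix(0L, 60, 90)
  tl[20:26, 10:16] <- 1L
  # territory 2: spans the notch of B; centroid lands in background but
  # exactly 50% of its pixels lie in B (boundary of the majority rule)
  tl[20:26, 52:83] <- 2L
  out <- assign_to_nuclei(
    structure(list(labels = tl), class = "ct_segmentation"), nuc)
  expect_equal(out$parent_nucleus[out$territory == 1], 1L)
  expect_equal(out$assign_method[out$territory == 1], "centroid")
  t2 <- out[out$territory == 2, ]
  expect_equal(t2$parent_nucleus, 2L)
  expect_equal(t2$assign_method, "majority")

  # narrower bridge: centroid in background and < 50% in any nucleus
  tl3 <- matrix(0L, 60, 90)
  tl3[20:26, 55:80] <- 3L           # 10 in-B columns of 26
  out3 <- assign_to_nuclei(
    structure(list(labels = tl3), class = "ct_segmentation"), nuc)
  expect_true(is.na(out3$parent_nucleus))
  expect_true(out3$flagged)
})
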