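const_img <- function(v, n = 16) calibrated_image(matrix(v, n, n), 1)

test_that("median filter computes exact window medians", {
  img <- const_img(0.4)
  expect_equal(median_filter(img, 3)$pixels, img$pixels)
  # isolated bright pixel is removed by a 3x3 median
  px <- matrix(0, 9, 9)
  px[5, 5] <- 1
  out <- median_filter(calibrated_image(px, 1), 3)
  expect_equal(out$pixels, matrix(0, 9, 9))
  # window 1 is the identity
  set.seed(1)
  rnd <- calibrated_image(matrix(runif(144), 12, 12), 2, time_h = 24)
  expect_identical(median_filter(rnd, 1), rnd)
  # brute-force oracle on the interior of a random image
  f <- median_filter(rnd, 3)$pixels
  ref <- rnd$pixels
  for (i in 2:11) {
    for (j in 2:11) {
      ref[i, j] <- median(rnd$pixels[(i - 1):(i + 1), (j - 1):(j + 1)])
    }
  }
  expect_equal(f[2:11, 2:11], ref[2:11, 2:11])
  # metadata preserved
  expect_equal(f <- median_filter(rnd, 3)$calibration, 2)
  expect_error(median_filter(rnd, 4), "odd")
  expect_error(median_filter(rnd, -3))
  expect_error(median_filter(rnd, 13), "dimensions")
})

test_that("sobel magnitude matches hand convolution", {
  expect_equal(sobel_magnitude(const_img(0.7))$pixels, matrix(0, 16, 16))
  # vertical unit step: |gx| = 4 on the two columns adjacent to the step
  px <- cbind(matrix(0, 8, 4), matrix(1, 8, 4))
  g <- sobel_magnitude(calibrated_image(px, 1))$pixels
  expect_equal(g[, 4], rep(4, 8))
  expect_equal(g[, 5], rep(4, 8))
  expect_equal(g[, c(1:3, 6:8)], matrix(0, 8, 6))
  # transpose symmetry of the kernel pair
  set.seed(2)
  a <- matrix(runif(100), 10, 10)
  expect_equal(
    sobel_magnitude(calibrated_image(t(a), 1))$pixels,
    t(sobel_magnitude(calibrated_image(a, 1))$pixels)
  )
})

test_that("segmentation recovers noise-free scenes exactly", {
  sc <- scene_spec(
    image_size = 512, n_pellet = 3, n_clump = 0, n_spore = 0,
    pellet_radius_um = c(40, 60), pellet_roughness = c(0, 0),
    pellet_aspect = c(1, 1), noise_sd = 0, seed = 31
  )
  scn <- make_scene(sc)
  masks <- segment_objects(scn$image, segmentation_config())
  expect_length(masks, 3)
  # areas within 2% of the analytic truth (median filtering may smooth a
  # few single-pixel boundary steps, so pixel sets need not be identical)
  a_found <- sort(vapply(masks, projected_area, numeric(1)))
  a_true <- sort(scn$truth$true_area_um2)
  expect_true(all(abs(a_found - a_true) / a_true < 0.02))
  placed <- sort(vapply(scn$masks, n_pixels, integer(1)))
  expect_true(all(abs(a_found - placed) / placed < 0.02))
})

test_that("segmented masks are disjoint, connected and sorted", {
  sc <- scene_spec(
    image_size = 400, n_pellet = 1, n_clump = 4, n_spore = 2,
    pellet_radius_um = c(40, 55), seed = 32
  )
  masks <- segment_objects(make_scene(sc)$image, segmentation_config())
  areas <- vapply(masks, n_pixels, integer(1))
  expect_equal(areas, sort(areas, decreasing = TRUE))
  keys <- unlist(lapply(masks, function(m) m$coords[, 1] * 1e5 + m$coords[, 2]))
  expect_equal(anyDuplicated(keys), 0L)
  for (m in masks) {
    expect_true(mycomorph:::mask_is_connected(m))
  }
})

test_that("blank and uniform images give empty segmentations", {
  expect_length(segment_objects(const_img(0.85, 64)), 0)
  expect_length(segment_objects(const_img(0, 64)), 0)
})

test_that("the area filter removes 10 um talc distractors", {
  sc <- scene_spec(
    image_size = 512, n_pellet = 1, n_clump = 0, n_spore = 0, n_talc = 5,
    pellet_radius_um = c(50, 70), noise_sd = 0, seed = 33
  )
  scn <- make_scene(sc)
  # a 10 um disk projects ~78.5 um^2 < 100
  masks <- segment_objects(
    scn$image, segmentation_config(min_area_um2 = 100)
  )
  expect_length(masks, 1)
  expect_gt(projected_area(masks[[1]]), 1e3)
  # with the default 20 um^2 floor the talc disks are kept
  all_masks <- segment_objects(scn$image, segmentation_config())
  expect_length(all_masks, 6)
})

test_that("segmentation tolerates noise at 5% of the contrast", {
  mk <- function(noise) {
    scene_spec(
      image_size = 512, n_pellet = 2, n_clump = 0, n_spore = 0,
      pellet_radius_um = c(40, 60), pellet_roughness = c(0, 0.2),
      noise_sd = noise, seed = 34
    )
  }
  clean <- segment_objects(make_scene(mk(0))$image, segmentation_config())
  # contrast = background 0.85 - pellet 0.25 = 0.6; 5% -> sd 0.03
  noisy <- segment_objects(make_scene(mk(0.03))$image, segmentation_config())
  expect_length(noisy, length(clean))
  a0 <- sort(vapply(clean, projected_area, numeric(1)))
  a1 <- sort(vapply(noisy, projected_area, numeric(1)))
  expect_true(all(abs(a1 - a0) / a0 < 0.05))
})

test_that("border policy and fixed thresholds behave as configured", {
  # one disk fully inside, one crossing the border
  px <- matrix(0.85, 120, 120)
  cc <- expand.grid(r = 1:120, c = 1:120)
  inside <- (cc$r - 60)^2 + (cc$c - 30)^2 <= 15^2
  crossing <- (cc$r - 2)^2 + (cc$c - 90)^2 <= 15^2
  px[as.matrix(cc[inside, ])] <- 0.2
  px[as.matrix(cc[crossing, ])] <- 0.2
  img <- calibrated_image(px, 1)
  excl <- segment_objects(img, segmentation_config(border = "exclude"))
  expect_length(excl, 1)
  expect_false(excl[[1]]$touches_border)
  flag <- segment_objects(img, segmentation_config(border = "flag"))
  expect_length(flag, 2)
  expect_equal(sum(vapply(flag, function(m) m$touches_border, logical(1))), 1L)
  fixed <- segment_objects(img, segmentation_config(threshold = 0.5))
  expect_length(fixed, 1)
})

test_that("segmentation output ignores image metadata", {
  sc <- scene_spec(image_size = 256, n_pellet = 1, n_clump = 2,
    pellet_radius_um = c(30, 40), seed = 35)
  img <- make_scene(sc)$image
  img2 <- img
  img2$id <- "renamed"
  img2$time_h <- 999
  m1 <- segment_objects(img, segmentation_config())
  m2 <- segment_objects(img2, segmentation_config())
  expect_equal(
    lapply(m1, function(m) m$coords),
    lapply(m2, function(m) m$coords)
  )
})

test_that("hole filling closes enclosed background", {
  px <- matrix(0.9, 60, 60)
  cc <- expand.grid(r = 1:60, c = 1:60)
  ring <- (cc$r - 30)^2 + (cc$c - 30)^2 <= 20^2
  core <- (cc$r - 30)^2 + (cc$c - 30)^2 <= 8^2
  px[as.matrix(cc[ring, ])] <- 0.2
  px[as.matrix(cc[core, ])] <- 0.9 # hole
  img <- calibrated_image(px, 1)
  filled <- segment_objects(img, segmentation_config(fill_holes = TRUE))
  open <- segment_objects(img, segmentation_config(fill_holes = FALSE))
  gained <- n_pixels(filled[[1]]) - n_pixels(open[[1]])
  expect_gt(gained, 0.9 * sum(core)) # hole closed (median-smoothed rim)
  # the filled mask has no enclosed background left
  bb <- mycomorph:::mask_bbox_matrix(filled[[1]])$m
  bglab <- mycomorph:::label_components_cpp(!bb, 4L)
  on_edge <- unique(c(
    bglab[1, ], bglab[nrow(bglab), ], bglab[, 1], bglab[, ncol(bglab)]
  ))
  expect_true(all(unique(as.vector(bglab[bglab > 0])) %in% on_edge))
})

test_that("connected labeling agrees with an independent implementation", {
  skip_if_not_installed("EBImage")
  set.seed(3)
  m <- matrix(runif(400) < 0.35, 20, 20)
  ours4 <- mycomorph:::label_components_cpp(m, 4L)
  ref4 <- EBImage::bwlabel(matrix(as.numeric(m), 20, 20))
  # same partition: label images identical up to renumbering
  expect_equal(max(ours4), max(ref4))
  expect_equal(
    tapply(ref4[m], ours4[m], function(v) length(unique(v))),
    tapply(ours4[m], ours4[m], function(v) 1), ignore_attr = TRUE
  )
})

test_that("images round-trip through TIFF and PNG", {
  sc <- scene_spec(image_size = 64, n_pellet = 0, n_clump = 2, seed = 36)
  img <- make_scene(sc)$image
  for (ext in c(".tif", ".png")) {
    p <- tempfile(fileext = ext)
    write_image(img, p)
    back <- read_image(p, img$calibration, img$time_h, img$talc_g_per_l)
    expect_equal(back$pixels, img$pixels, tolerance = 1 / 255)
  }
})
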