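test_that("projected area is pixel count times squared calibration", {
  m <- rect_mask(10, 10, cal = 1.5)
  expect_equal(projected_area(m), 100 * 1.5^2)
  expect_equal(projected_area(object_mask(cbind(0L, 0L), 1)), 1)
  disk <- make_pellet_mask(50, 0, 1, 1, seed = 1)
  expect_lt(abs(projected_area(disk) - pi * 2500) / (pi * 2500), 0.02)
  expect_error(object_mask(matrix(numeric(0), 0, 2), 1), "at least one")
})

test_that("elongation is the squared principal deviation ratio", {
  disk <- make_pellet_mask(60, 0, 1, 1, seed = 2)
  expect_lt(abs(elongation(disk) - 1), 0.02)
  rect <- rect_mask(100, 25)
  expect_lt(abs(elongation(rect) - 16) / 16, 0.05)
  ell <- ellipse_mask(80, 40)
  expect_lt(abs(elongation(ell) - 4) / 4, 0.05)
  # degenerate: a 1-pixel-wide straight line has no transversal spread
  line <- object_mask(cbind(0:20, 0L), 1)
  expect_error(elongation(line), "degenerate")
})

test_that("solidity is area over pixel-square convex hull area", {
  expect_equal(solidity(rect_mask(30, 40)), 1)
  # L-tromino: hull polygon (0,0),(2,0),(2,1),(1,2),(0,2), area 3.5
  tro <- object_mask(rbind(c(0, 0), c(1, 0), c(0, 1)), 1)
  expect_equal(solidity(tro), 3 / 3.5, tolerance = 1e-12)
  disk <- make_pellet_mask(50, 0, 1, 1, seed = 3)
  expect_gte(solidity(disk), 0.98)
})

test_that("maximum diameter is the Feret maximum over pixel corners", {
  rect <- rect_mask(30, 40)
  expect_equal(max_diameter(rect), 50, tolerance = 1e-12)
  one <- object_mask(cbind(0L, 0L), calibration = 2)
  expect_equal(max_diameter(one), 2 * sqrt(2))
  disk <- make_pellet_mask(50, 0, 1, 1, seed = 4)
  expect_lt(abs(max_diameter(disk) - 101) / 101, 0.02)
})

test_that("morphology number follows the closed form and its bounds", {
  # perfect disk values cancel exactly
  expect_equal(morphology_number(pi * 100^2, 1, 200, 1), 1)
  expect_equal(morphology_number(1e4, 0.9, 150, 2), 180 / (sqrt(pi) * 300),
    tolerance = 1e-12
  )
  base <- morphology_number(1e4, 0.9, 150, 1.5)
  expect_equal(morphology_number(1e4, 0.9, 150, 3), base / 2)
  expect_error(morphology_number(-1, 0.9, 100, 1))
  expect_error(morphology_number(1e4, 1.2, 100, 1), "solidity")
  expect_error(morphology_number(1e4, 0.9, 100, 0.5), "elongation")
  # inconsistent descriptors (tiny D) must raise, not clamp
  expect_error(morphology_number(1e4, 1, 10, 1), "exceeds 1")
})

test_that("descriptors equal brute-force recomputation on small masks", {
  masks <- c(
    list(
      rect_mask(7, 19), ellipse_mask(12, 5),
      object_mask(rbind(c(0, 0), c(1, 0), c(0, 1)), 1)
    ),
    random_mask_suite(3, seed = 50)
  )
  masks <- Filter(function(m) n_pixels(m) <= 400, masks)
  expect_gt(length(masks), 4)
  for (m in masks) {
    expect_equal(solidity(m), oracle_solidity(m), tolerance = 1e-9)
    expect_equal(max_diameter(m), oracle_max_diameter(m), tolerance = 1e-9)
    expect_equal(elongation(m), oracle_elongation(m), tolerance = 1e-9)
    expect_equal(projected_area(m), n_pixels(m) * m$calibration^2)
  }
})

test_that("descriptor bounds hold across randomized masks", {
  for (m in random_mask_suite(10, seed = 7)) {
    v <- measure_mask(m)
    expect_gte(v["E"], 1)
    expect_gt(v["S"], 0)
    expect_lte(v["S"], 1 + 0.02)
    expect_gt(v["Mo"], 0)
    expect_lte(v["Mo"], 1 + 0.02)
  }
})

test_that("disk morphology number converges to 1 with radius", {
  radii <- c(10, 25, 50, 100, 200)
  mo <- vapply(radii, function(r) {
    m <- make_pellet_mask(r, 0, 1, 1, seed = 11)
    v <- measure_mask(m)
    v[["Mo"]]
  }, numeric(1))
  expect_true(all(diff(mo) > -0.005)) # monotone up to rasterization noise
  expect_lt(abs(mo[length(mo)] - 1), 0.02)
})

test_that("calibration scaling is exactly equivariant", {
  rc <- make_pellet_mask(30, 0.2, 1.3, 1, seed = 5)$coords
  m1 <- object_mask(rc, calibration = 1)
  m2 <- object_mask(rc, calibration = 2)
  expect_equal(projected_area(m2), 4 * projected_area(m1))
  expect_equal(max_diameter(m2), 2 * max_diameter(m1))
  expect_equal(elongation(m2), elongation(m1))
  expect_equal(solidity(m2), solidity(m1))
  v1 <- measure_mask(m1)
  v2 <- measure_mask(m2)
  expect_equal(v2[["Mo"]], v1[["Mo"]])
})

test_that("shape descriptors are robust to rotation", {
  vals <- sapply(seq(0, pi * 0.9, length.out = 6), function(ang) {
    m <- make_pellet_mask(40, 0, 2, 1, seed = 21, angle = ang)
    measure_mask(m)[c("E", "S", "Mo")]
  })
  spread <- apply(vals, 1, function(v) diff(range(v)) / mean(v))
  expect_true(all(spread < 0.05))
})

test_that("elongation recovers the generator's squared aspect ratio", {
  est <- vapply(1:20, function(i) {
    elongation(make_pellet_mask(35, 0, 2, 1, seed = 400 + i, angle = i))
  }, numeric(1))
  expect_lt(abs(mean(est) - 4) / 4, 0.10)
})

test_that("classification applies the area decision rule", {
  expect_identical(classify_area(164, 24), "clump_hyphae")
  expect_identical(classify_area(1e5, 96), "pellet")
  expect_identical(classify_area(50, 0), "spore")
  expect_identical(classify_area(10, 48), "debris")
  # boundary inclusive on the clump side; spores only at 0 h
  th <- morpho_thresholds()
  expect_identical(classify_area(th$pellet_min_um2, 24), "clump_hyphae")
  expect_identical(classify_area(th$pellet_min_um2 + 1, 24), "pellet")
  expect_identical(classify_area(50, 24), "clump_hyphae")
  # every object receives a class
  cls <- classify_area(10^runif(50, 0, 6), sample(c(0, 24, 96), 50, TRUE))
  expect_true(all(cls %in% c("debris", "spore", "clump_hyphae", "pellet")))
})

test_that("group summaries report n, mean, SD, band and the n>=30 flag", {
  rec <- data.frame(
    time_h = 24, talc_g_per_L = 5,
    A_um2 = rep(100, 30), E = 1.5, S = 0.9, D_um = 12,
    Mo = rep(c(0.2, 0.4), 15), class = "clump_hyphae"
  )
  s30 <- summarize_morphology(rec)
  expect_true(all(s30$sufficient_n))
  expect_equal(s30$mean[s30$param == "Mo"], 0.3)
  s29 <- summarize_morphology(rec[1:29, ])
  expect_false(any(s29$sufficient_n))
  # identical values: zero SD and zero-width band containing the mean
  arow <- s30[s30$param == "A", ]
  expect_equal(arow$sd, 0)
  expect_equal(arow$ci_lo, arow$mean)
  expect_equal(arow$ci_hi, arow$mean)
})
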