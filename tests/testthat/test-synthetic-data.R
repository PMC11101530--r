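test_that("scenes contain exactly the requested objects", {
  sc <- scene_spec(
    image_size = 700, n_pellet = 5, n_clump = 0, n_spore = 0,
    pellet_radius_um = c(40, 60), seed = 41
  )
  scn <- make_scene(sc)
  expect_equal(nrow(scn$truth), 5)
  expect_true(all(scn$truth$class == "pellet"))
  expect_true(all(scn$truth$true_area_um2 > 0))
  expect_equal(scn$truth$object_id, 1:5)
})

test_that("scene generation is a pure function of the spec", {
  sc <- scene_spec(image_size = 300, n_pellet = 1, n_clump = 3,
    n_spore = 2, pellet_radius_um = c(30, 45), seed = 42)
  s1 <- make_scene(sc)
  s2 <- make_scene(sc)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth, s2$truth)
})

test_that("pellet aspect ratio controls the second-moment ratio", {
  m <- make_pellet_mask(60, 0, 2, 1, seed = 43)
  ev <- oracle_eigvals(m$coords)
  expect_lt(abs(ev[1] / ev[2] - 4) / 4, 0.05)
})

test_that("pellet masks rasterize disks faithfully", {
  m <- make_pellet_mask(50, 0, 1, calibration = 1, seed = 44)
  expect_lt(abs(n_pixels(m) - pi * 50^2) / (pi * 50^2), 0.02)
  expect_gte(solidity(m), 0.98)
  m2 <- make_pellet_mask(50, 0, 1, calibration = 1, seed = 44)
  expect_identical(m$coords, m2$coords)
  expect_error(make_pellet_mask(0.4, 0, 1, 1, seed = 1), "one pixel")
  expect_error(make_pellet_mask(10, 1.2, 1, 1, seed = 1))
  expect_error(make_pellet_mask(10, 0, 0.5, 1, seed = 1))
})

test_that("filament masks are elongated, connected and deterministic", {
  f <- make_filament_mask(100, 3, 0, 1, seed = 45)
  expect_gte(elongation(f), 4)
  expect_gte(max_diameter(f), 80) # curvature allowance of 20%
  expect_true(mycomorph:::mask_is_connected(f))
  expect_equal(attr(f, "n_branches"), 0L)
  f2 <- make_filament_mask(100, 3, 0, 1, seed = 45)
  expect_identical(f$coords, f2$coords)
  fb <- make_filament_mask(40, 3, 1, 1, seed = 46)
  expect_equal(attr(fb, "n_branches"), 3L)
  # area stays within the branching allowance
  expect_lte(n_pixels(fb), 40 * 3 * (1 + 3 * 0.30) + 3^2 * pi)
  expect_error(make_filament_mask(10, 0.4, 0, 1, seed = 1), "one pixel")
  expect_error(make_filament_mask(2, 3, 0, 1, seed = 1))
})

test_that("generated mask areas agree with the reported ground truth", {
  suite <- c(
    lapply(1:6, function(i) {
      make_pellet_mask(20 + 10 * i, 0.1 + 0.04 * i, 1 + i / 6, 1,
        seed = 500 + i, angle = i
      )
    }),
    lapply(1:6, function(i) {
      make_filament_mask(40 + 8 * i, 2.5 + 0.2 * i, 0.3, 1, seed = 520 + i)
    })
  )
  for (m in suite) {
    if (n_pixels(m) < 100) next
    ta <- attr(m, "true_area_um2")
    expect_lt(abs(projected_area(m) - ta) / ta, 0.05)
  }
})

test_that("default class parameter ranges respect the observed group areas", {
  # clumps/hyphae stay below 164 um^2, pellets within 1e4-1e6 um^2
  sc <- scene_spec(seed = 47)
  for (i in 1:25) {
    cl <- make_filament_mask(
      runif(1, sc$clump_length_um[1], sc$clump_length_um[2]),
      runif(1, sc$clump_width_um[1], sc$clump_width_um[2]),
      sc$branch_probability, sc$calibration,
      seed = 600 + i
    )
    expect_lte(attr(cl, "true_area_um2"), 164)
  }
  for (i in 1:8) {
    pe <- make_pellet_mask(
      runif(1, sc$pellet_radius_um[1], sc$pellet_radius_um[2]),
      runif(1, sc$pellet_roughness[1], sc$pellet_roughness[2]),
      runif(1, sc$pellet_aspect[1], sc$pellet_aspect[2]),
      sc$calibration,
      seed = 700 + i
    )
    expect_gte(attr(pe, "true_area_um2"), 1e4)
    expect_lte(attr(pe, "true_area_um2"), 1e6)
  }
})

test_that("impossible placements raise an error naming the class", {
  sc <- scene_spec(
    image_size = 150, n_pellet = 4, n_clump = 0,
    pellet_radius_um = c(60, 70), seed = 48
  )
  expect_error(make_scene(sc), "pellet")
})

test_that("time series encode the true enhancement factor exactly when noiseless", {
  tms <- c(0, 24, 48, 72, 96)
  tss <- timeseries_spec(
    metabolites = "m1", conditions = c(0, 5), replicates = 4,
    control_means = matrix(2, 1, 5, dimnames = list("m1", tms)),
    true_ef = array(rep(c(1, 9), each = 5), c(1, 5, 2),
      dimnames = list("m1", tms, c(0, 5))
    ),
    cv = 0, glucose_sd = 0, seed = 49
  )
  ts <- make_timeseries(tss)
  trt <- ts$m1[ts$talc_g_per_L == 5]
  ctl <- ts$m1[ts$talc_g_per_L == 0]
  expect_equal(trt, 9 * ctl)
  # EF = 1 everywhere makes both arms identical in the noiseless limit
  tss1 <- timeseries_spec(
    metabolites = "m1", conditions = c(0, 5), replicates = 4,
    control_means = matrix(2, 1, 5, dimnames = list("m1", tms)),
    true_ef = array(1, c(1, 5, 2), dimnames = list("m1", tms, c(0, 5))),
    cv = 0, glucose_sd = 0, seed = 49
  )
  ts1 <- make_timeseries(tss1)
  expect_equal(
    ts1$m1[ts1$talc_g_per_L == 5], ts1$m1[ts1$talc_g_per_L == 0]
  )
})

test_that("replicate noise reproduces the requested coefficient of variation", {
  tms <- c(0, 24, 48, 72, 96)
  tss <- timeseries_spec(
    metabolites = "m1", conditions = 0, replicates = 1000,
    control_means = matrix(5, 1, 5, dimnames = list("m1", tms)),
    true_ef = array(1, c(1, 5, 1), dimnames = list("m1", tms, 0)),
    cv = 0.2, seed = 50
  )
  ts <- make_timeseries(tss)
  v <- ts$m1[ts$time_h == 48]
  cv_hat <- sd(v) / mean(v)
  expect_lt(abs(cv_hat - 0.2) / 0.2, 0.10)
})

test_that("glucose curves are non-increasing and non-negative", {
  tss <- timeseries_spec(seed = 51)
  for (cond in tss$conditions) {
    g <- glucose_curve(tss, cond, seq(0, 96, by = 1))
    expect_true(all(diff(g) <= 1e-12))
  }
  ts <- make_timeseries(tss)
  expect_true(all(ts$glucose_g_per_L >= 0))
  expect_true(all(vapply(ts[tss$metabolites], function(v) all(v >= 0), TRUE)))
})

test_that("invalid time-series specs are rejected", {
  tms <- c(0, 24, 48, 72, 96)
  expect_error(
    timeseries_spec(
      metabolites = "m1",
      control_means = matrix(-1, 1, 5, dimnames = list("m1", tms))
    ),
    "control means"
  )
  expect_error(timeseries_spec(cv = -0.1))
  expect_error(timeseries_spec(glucose_initial = 5), "non-increasing")
})

test_that("time series generation is deterministic and CSV round-trips", {
  tss <- timeseries_spec(replicates = 2, seed = 52)
  t1 <- make_timeseries(tss)
  t2 <- make_timeseries(tss)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  p <- tempfile(fileext = ".csv")
  write_timeseries_csv(t1, p)
  back <- read_timeseries_csv(p)
  ref <- as.data.frame(t1)
  attr(ref, "spec") <- NULL
  rownames(ref) <- NULL
  expect_equal(as.data.frame(back), ref, tolerance = 1e-12)
})
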