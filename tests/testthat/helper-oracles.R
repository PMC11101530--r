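# Brute-force oracles recomputing every descriptor directly from the raw
# pixel set, independently of the implementation paths (closed-form
# eigenvalues instead of LAPACK, all-corner hulls instead of
# boundary-corner hulls, all-pairs distances instead of hull pairs).

oracle_eigvals <- function(coords) {
  mu <- colMeans(coords)
  d <- sweep(coords, 2, mu)
  m20 <- mean(d[, 1]^2)
  m02 <- mean(d[, 2]^2)
  m11 <- mean(d[, 1] * d[, 2])
  half_tr <- (m20 + m02) / 2
  disc <- sqrt(max(0, half_tr^2 - (m20 * m02 - m11^2)))
  c(half_tr + disc, half_tr - disc)
}

oracle_elongation <- function(mask) {
  ev <- oracle_eigvals(mask$coords)
  ev[1] / ev[2]
}

all_corners <- function(mask) {
  rc <- mask$coords
  unique(rbind(
    rc,
    cbind(rc[, 1] + 1L, rc[, 2]),
    cbind(rc[, 1], rc[, 2] + 1L),
    cbind(rc[, 1] + 1L, rc[, 2] + 1L)
  ))
}

shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}

oracle_solidity <- function(mask) {
  pts <- all_corners(mask)
  h <- grDevices::chull(pts)
  nrow(mask$coords) / shoelace(pts[h, , drop = FALSE])
}

oracle_max_diameter <- function(mask) {
  max(dist(all_corners(mask))) * mask$calibration
}

# simple independent rasterizers (pixel centres on the integer lattice)
rect_mask <- function(h, w, cal = 1) {
  object_mask(
    as.matrix(expand.grid(row = 0:(h - 1), col = 0:(w - 1))),
    calibration = cal
  )
}

ellipse_mask <- function(a, b, cal = 1) {
  # semi-axes: a along columns, b along rows
  g <- expand.grid(row = -(b + 1):(b + 1), col = -(a + 1):(a + 1))
  keep <- (g$col / a)^2 + (g$row / b)^2 <= 1
  rc <- as.matrix(g[keep, ])
  rc[, 1] <- rc[, 1] - min(rc[, 1])
  rc[, 2] <- rc[, 2] - min(rc[, 2])
  object_mask(rc, calibration = cal)
}

measure_mask <- function(mask) {
  a <- projected_area(mask)
  s <- solidity(mask)
  d <- max_diameter(mask)
  e <- elongation(mask)
  c(A = a, S = s, D = d, E = e, Mo = morphology_number(a, s, d, e))
}

# a small randomized suite of masks spanning all generator classes
random_mask_suite <- function(n_per_class, seed = 1L) {
  masks <- list()
  k <- 0L
  for (i in seq_len(n_per_class)) {
    k <- k + 1L
    masks[[k]] <- make_pellet_mask(
      radius_um = 10 + 50 * (i / n_per_class), 0, 1, 1,
      seed = seed + i
    )
    k <- k + 1L
    masks[[k]] <- make_pellet_mask(
      radius_um = 15 + 30 * (i / n_per_class), 0,
      aspect_ratio = 1 + 3 * (i / n_per_class), 1,
      seed = seed + 100 + i, angle = i
    )
    k <- k + 1L
    masks[[k]] <- make_pellet_mask(
      radius_um = 20 + 40 * (i / n_per_class),
      roughness_amplitude = 0.05 + 0.4 * (i / n_per_class), 1.2, 1,
      seed = seed + 200 + i, angle = i / 2
    )
    k <- k + 1L
    masks[[k]] <- make_filament_mask(
      length_um = 20 + 60 * (i / n_per_class),
      width_um = 2 + 2 * (i / n_per_class),
      branch_probability = (i %% 3) / 3, 1,
      seed = seed + 300 + i, angle = i / 3
    )
  }
  masks
}
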