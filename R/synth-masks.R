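## Seeded generators for single object masks with analytic ground truth.

# low-order random radial perturbation, normalised so |pert(theta)| <= 1;
# returns a function of theta (radians)
radial_perturbation <- function(kmax = 6L) {
  ks <- 2:kmax
  amp <- rnorm(length(ks))
  phi <- runif(length(ks), 0, 2 * pi)
  w <- 1 / ks
  norm <- sum(abs(amp) * w)
  if (norm < 1e-12) {
    return(function(theta) rep(0, length(theta)))
  }
  amp <- amp / norm
  function(theta) {
    out <- 0
    for (i in seq_along(ks)) {
      out <- out + amp[i] * w[i] * cos(ks[i] * theta + phi[i])
    }
    out
  }
}

#' Generate a pellet-like mask
#'
#' Rasterizes a pellet: a disk of radius `radius_um` whose boundary is
#' perturbed by a periodic radial function
#' `r(theta) = r0 * (1 + amplitude * sum of low-order random harmonics)`
#' (harmonics 2-6, normalised so the perturbation never exceeds
#' `amplitude`), optionally stretched to a target aspect ratio by an
#' area-preserving transform (long semi-axis `r*sqrt(aspect)`, short
#' `r/sqrt(aspect)`, so the ratio of principal second moments is
#' `aspect^2`). With `roughness_amplitude = 0` and `aspect_ratio = 1`
#' the mask is a rasterized disk. Also used for spores (small radii).
#'
#' @param radius_um Base radius in um, > 0 and at least one pixel.
#' @param roughness_amplitude Relative boundary perturbation in `[0, 1)`.
#' @param aspect_ratio Target aspect ratio, >= 1.
#' @param calibration Micrometres per pixel, > 0.
#' @param seed Integer seed; identical arguments and seed give identical
#'   pixel sets.
#' @param angle Orientation of the long axis, radians (default 0).
#' @return An [object_mask] with attributes `true_area_um2` (analytic
#'   polygon area of the generating boundary) and `true_aspect`.
#' @examples
#' m <- make_pellet_mask(50, 0.2, 1.5, calibration = 1, seed = 7)
#' attr(m, "true_area_um2")
#' @export
make_pellet_mask <- function(radius_um, roughness_amplitude = 0,
                             aspect_ratio = 1, calibration = 1,
                             seed = 1L, angle = 0) {
  stop_if_not_scalar_num(radius_um, "radius_um", 0, strict = TRUE)
  stop_if_not_scalar_num(calibration, "calibration", 0, strict = TRUE)
  if (roughness_amplitude < 0 || roughness_amplitude >= 1) {
    stop("'roughness_amplitude' must be in [0, 1)", call. = FALSE)
  }
  if (aspect_ratio < 1) {
    stop("'aspect_ratio' must be >= 1", call. = FALSE)
  }
  r0 <- radius_um / calibration
  if (r0 < 1) {
    stop("radius is smaller than one pixel at this calibration",
      call. = FALSE
    )
  }
  with_seed(seed, {
    pert <- radial_perturbation()
    rfun <- function(theta) r0 * (1 + roughness_amplitude * pert(theta))
    # analytic area of the generating region: 0.5 * int r(theta)^2 dtheta;
    # the aspect transform and rotation are area-preserving
    th <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
    true_area_px <- 0.5 * mean(rfun(th)^2) * 2 * pi
    half_x <- r0 * (1 + roughness_amplitude) * sqrt(aspect_ratio) + 2
    n <- ceiling(half_x)
    ctr <- seq(-n, n) + 0.5
    px <- rep(ctr, each = length(ctr)) # x = column direction
    py <- rep(ctr, times = length(ctr)) # y = row direction
    ca <- cos(angle)
    sa <- sin(angle)
    xr <- ca * px + sa * py
    yr <- -sa * px + ca * py
    u <- xr / sqrt(aspect_ratio)
    v <- yr * sqrt(aspect_ratio)
    inside <- sqrt(u^2 + v^2) <= rfun(atan2(v, u))
    rows <- rep(seq_len(length(ctr)) - 1L, times = length(ctr))[inside]
    cols <- rep(seq_len(length(ctr)) - 1L, each = length(ctr))[inside]
    m <- largest_component(cbind(rows, cols))
    out <- object_mask(m, calibration = calibration)
    attr(out, "true_area_um2") <- true_area_px * calibration^2
    attr(out, "true_aspect") <- aspect_ratio
    out
  })
}

# keep the largest 8-connected component of a pixel set (guards against
# rare pinch-offs of strongly perturbed boundaries)
largest_component <- function(coords) {
  r0 <- min(coords[, 1])
  c0 <- min(coords[, 2])
  m <- matrix(FALSE, max(coords[, 1]) - r0 + 1L, max(coords[, 2]) - c0 + 1L)
  m[cbind(coords[, 1] - r0 + 1L, coords[, 2] - c0 + 1L)] <- TRUE
  lab <- label_components_cpp(m, 8L)
  if (max(lab) > 1L) {
    keep <- which.max(tabulate(lab[lab > 0]))
    idx <- which(lab == keep, arr.ind = TRUE)
    coords <- cbind(idx[, 1] - 1L + r0, idx[, 2] - 1L + c0)
  }
  # re-origin at zero
  cbind(coords[, 1] - min(coords[, 1]), coords[, 2] - min(coords[, 2]))
}

#' Generate a filament (hypha/clump) mask
#'
#' Rasterizes a gently curved filament of the given length and width
#' (a capsule around a random smooth path whose total bend is bounded,
#' so the end-to-end distance stays above 80% of the path length), with
#' optional straight side branches: each of three interior sites (25,
#' 50, 75% along the path) spawns a branch with probability
#' `branch_probability`, of length 15-30% of the main length. With
#' `branch_probability = 0` the mask is a single unbranched strand.
#'
#' @param length_um Path length in um, >= `width_um`.
#' @param width_um Strand width in um, > 0 and at least one pixel.
#' @param branch_probability Per-site branching probability in `[0, 1]`.
#' @param calibration Micrometres per pixel, > 0.
#' @param seed Integer seed.
#' @param angle Initial heading, radians (default 0).
#' @return An [object_mask] with attributes `true_area_um2` (3x
#'   supersampled subpixel area) and `true_aspect` (length/width).
#' @export
make_filament_mask <- function(length_um, width_um, branch_probability = 0,
                               calibration = 1, seed = 1L, angle = 0) {
  stop_if_not_scalar_num(length_um, "length_um", 0, strict = TRUE)
  stop_if_not_scalar_num(width_um, "width_um", 0, strict = TRUE)
  if (length_um < width_um) {
    stop("'length_um' must be >= 'width_um'", call. = FALSE)
  }
  if (branch_probability < 0 || branch_probability > 1) {
    stop("'branch_probability' must be in [0, 1]", call. = FALSE)
  }
  w_px <- width_um / calibration
  if (w_px < 1) {
    stop("width is smaller than one pixel at this calibration",
      call. = FALSE
    )
  }
  len_px <- length_um / calibration
  with_seed(seed, {
    ds <- 0.25
    s <- seq(0, len_px, by = ds)
    # smooth bounded heading perturbation: two low-frequency modes whose
    # combined amplitude stays below 0.35 rad
    b <- runif(2)
    b <- 0.35 * b / max(1, sum(b))
    p <- runif(2, 0, 2 * pi)
    theta <- angle + b[1] * sin(2 * pi * s / len_px + p[1]) +
      b[2] * sin(4 * pi * s / len_px + p[2])
    pts <- cbind(cumsum(ds * cos(theta)), cumsum(ds * sin(theta)))
    pts <- rbind(c(0, 0), pts[-nrow(pts), , drop = FALSE])
    all_pts <- pts
    n_branch <- 0L
    if (branch_probability > 0) {
      sites <- round(c(0.25, 0.5, 0.75) * nrow(pts))
      for (k in sites) {
        if (runif(1) < branch_probability) {
          n_branch <- n_branch + 1L
          bl <- runif(1, 0.15, 0.30) * len_px
          ba <- theta[k] + sample(c(-1, 1), 1) * runif(1, 0.5, 1.0)
          sb <- seq(0, bl, by = ds)
          all_pts <- rbind(all_pts, cbind(
            pts[k, 1] + sb * cos(ba),
            pts[k, 2] + sb * sin(ba)
          ))
        }
      }
    }
    # rasterize on a 3x supersampled grid; the centre subsample of each
    # pixel decides mask membership, all nine give the subpixel area
    lo <- floor(apply(all_pts, 2, min) - w_px / 2 - 1)
    hi <- ceiling(apply(all_pts, 2, max) + w_px / 2 + 1)
    nx <- hi[1] - lo[1] + 1
    ny <- hi[2] - lo[2] + 1
    sub <- (seq_len(3 * nx) - 0.5) / 3 + lo[1]
    suby <- (seq_len(3 * ny) - 0.5) / 3 + lo[2]
    gx <- rep(sub, times = length(suby))
    gy <- rep(suby, each = length(sub))
    mind2 <- rep(Inf, length(gx))
    for (i in seq_len(nrow(all_pts))) {
      d2 <- (gx - all_pts[i, 1])^2 + (gy - all_pts[i, 2])^2
      mind2 <- pmin(mind2, d2)
    }
    hit <- mind2 <= (w_px / 2)^2
    true_area_px <- sum(hit) / 9
    hitm <- matrix(hit, nrow = 3 * nx)
    centre <- hitm[seq(2, 3 * nx, by = 3), seq(2, 3 * ny, by = 3),
      drop = FALSE
    ]
    idx <- which(centre, arr.ind = TRUE)
    # x indexes columns of the image, y rows
    m <- largest_component(cbind(idx[, 2] - 1L, idx[, 1] - 1L))
    out <- object_mask(m, calibration = calibration)
    attr(out, "true_area_um2") <- true_area_px * calibration^2
    attr(out, "true_aspect") <- length_um / width_um
    attr(out, "n_branches") <- n_branch
    out
  })
}
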