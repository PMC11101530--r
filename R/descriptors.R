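#' Projected area of an object
#'
#' `A` = number of pixels in the object times the squared calibration
#' unit, in um^2.
#'
#' @param mask An [object_mask].
#' @return Projected area in um^2.
#' @examples
#' m <- make_pellet_mask(50, 0, 1, calibration = 1, seed = 1)
#' projected_area(m) / (pi * 50^2) # ~ 1
#' @export
projected_area <- function(mask) {
  stopifnot(inherits(mask, "object_mask"))
  nrow(mask$coords) * mask$calibration^2
}

#' Elongation of an object
#'
#' Squared ratio of the longitudinal to the transversal deviation of all
#' object pixels about the orthogonal regression line (the major
#' principal axis): `E = (sigma_L / sigma_T)^2 >= 1`. Equal to 1 for a
#' disk; for a filled a x b rectangle it approaches `(a/b)^2`.
#'
#' @param mask An [object_mask] with at least 3 pixels and non-degenerate
#'   transversal spread.
#' @return Elongation, dimensionless, >= 1.
#' @export
elongation <- function(mask) {
  stopifnot(inherits(mask, "object_mask"))
  rc <- mask$coords
  if (nrow(rc) < 3L) {
    stop("elongation needs at least 3 pixels", call. = FALSE)
  }
  mu <- colMeans(rc)
  dr <- rc[, 1] - mu[1]
  dc <- rc[, 2] - mu[2]
  m20 <- mean(dr * dr)
  m02 <- mean(dc * dc)
  m11 <- mean(dr * dc)
  ev <- eigen(matrix(c(m20, m11, m11, m02), 2L), symmetric = TRUE,
    only.values = TRUE)$values
  if (ev[2] < 1e-9) {
    stop("degenerate object: transversal deviation is ~0", call. = FALSE)
  }
  ev[1] / ev[2]
}

#' Solidity (roughness) of an object
#'
#' Object area relative to the area of its convex hull, `S = A / A_hull`,
#' in `(0, 1]`; identical to the roughness descriptor `R`. The hull is
#' taken over the corner points of the object's pixel squares so that the
#' numerator (pixel count) and denominator use the same area convention.
#'
#' @param mask An [object_mask].
#' @return Solidity, dimensionless, in `(0, 1]`.
#' @export
solidity <- function(mask) {
  stopifnot(inherits(mask, "object_mask"))
  hull <- mask_hull(mask)
  ha <- polygon_area(hull)
  if (ha <= 0) {
    # degenerate (single row/column of pixels): hull collapses only if
    # the pixel squares are collinear, which cannot happen for unit
    # squares; guard anyway
    return(1)
  }
  nrow(mask$coords) / ha
}

#' Maximum (Feret) diameter of an object
#'
#' Largest distance between any two corner points of the object's pixel
#' squares, times the calibration. A single pixel has `D = sqrt(2)` times
#' the calibration (its square's diagonal).
#'
#' @param mask An [object_mask].
#' @return Maximum diameter in um.
#' @export
max_diameter <- function(mask) {
  stopifnot(inherits(mask, "object_mask"))
  hull <- mask_hull(mask)
  d2 <- max(dist(hull))
  d2 * mask$calibration
}

#' Morphology number
#'
#' Dimensionless composite descriptor
#' `Mo = 2 * sqrt(A) * S / (sqrt(pi) * D * E)`, in `(0, 1]`: 1 for a
#' perfect circle, decreasing for elongated or irregular objects. The
#' upper bound follows from the isodiametric inequality together with
#' `S <= 1` and `E >= 1`; a value above `1 + tol` indicates a descriptor
#' bug and raises an error rather than being clamped.
#'
#' @param a Projected area (um^2), > 0.
#' @param s Solidity in `(0, 1]` (up to `tol`).
#' @param d Maximum diameter (um), > 0.
#' @param e Elongation, >= 1 (up to `tol`).
#' @param tol Rasterization tolerance on the `S <= 1`, `E >= 1` and
#'   `Mo <= 1` checks (default 2%).
#' @return Morphology number, dimensionless.
#' @examples
#' morphology_number(pi * 100^2, 1, 200, 1) # exactly 1
#' @export
morphology_number <- function(a, s, d, e, tol = 0.02) {
  stop_if_not_scalar_num(a, "a", 0, strict = TRUE)
  stop_if_not_scalar_num(d, "d", 0, strict = TRUE)
  stop_if_not_scalar_num(s, "s", 0, strict = TRUE)
  stop_if_not_scalar_num(e, "e", 0, strict = TRUE)
  if (s > 1 + tol) {
    stop("solidity exceeds 1 beyond tolerance", call. = FALSE)
  }
  if (e < 1 - tol) {
    stop("elongation below 1 beyond tolerance", call. = FALSE)
  }
  mo <- 2 * sqrt(a) * s / (sqrt(pi) * d * e)
  if (mo > 1 + tol) {
    stop(sprintf(
      "morphology number %.4f exceeds 1 beyond tolerance; inconsistent descriptors",
      mo
    ), call. = FALSE)
  }
  mo
}

#' Measure all shape descriptors for a set of masks
#'
#' Computes, per object, the projected area `A`, elongation `E`,
#' solidity `S`, maximum diameter `D` and morphology number `Mo`.
#' Objects whose elongation is degenerate (e.g. a 1-pixel-wide straight
#' line) get `NA` descriptors and can be filtered downstream.
#'
#' @param masks List of [object_mask] objects.
#' @param time_h Sampling time recorded in every row (h).
#' @param talc_g_per_l Talc concentration recorded in every row (g/L).
#' @param image_id Image identifier recorded in every row.
#' @return A data.frame with columns `image_id`, `object_id`, `time_h`,
#'   `talc_g_per_L`, `A_um2`, `E`, `S`, `D_um`, `Mo`, `n_pixels`,
#'   `touches_border`.
#' @export
measure_objects <- function(masks, time_h = NA_real_,
                            talc_g_per_l = NA_real_, image_id = "img") {
  rows <- lapply(masks, function(m) {
    a <- projected_area(m)
    s <- solidity(m)
    d <- max_diameter(m)
    e <- tryCatch(elongation(m), error = function(err) NA_real_)
    mo <- if (is.na(e)) NA_real_ else morphology_number(a, s, d, e)
    data.frame(
      image_id = as.character(image_id), object_id = m$id,
      time_h = time_h, talc_g_per_L = talc_g_per_l,
      A_um2 = a, E = e, S = s, D_um = d, Mo = mo,
      n_pixels = n_pixels(m), touches_border = m$touches_border
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(
      image_id = character(), object_id = integer(), time_h = numeric(),
      talc_g_per_L = numeric(), A_um2 = numeric(), E = numeric(),
      S = numeric(), D_um = numeric(), Mo = numeric(),
      n_pixels = integer(), touches_border = logical()
    ))
  }
  do.call(rbind, rows)
}
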