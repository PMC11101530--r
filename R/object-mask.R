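#' Segmented object mask
#'
#' One connected segmented object, stored as the set of its pixel
#' coordinates (0-based `row`, `col`) plus the image calibration. All
#' shape descriptors operate on this representation; the continuous-space
#' convention is that pixel `(r, c)` occupies the unit square
#' `[r, r+1] x [c, c+1]`.
#'
#' @param coords Integer matrix with two columns (row, col), 0-based.
#' @param calibration Micrometres per pixel, > 0.
#' @param id Integer object id.
#' @param touches_border Logical, whether the object touches the image
#'   border.
#' @param validate Check 8-connectivity (costs a labeling pass over the
#'   bounding box; skipped by internal callers that construct connected
#'   sets).
#' @return An object of class `object_mask`.
#' @examples
#' m <- object_mask(cbind(c(0, 0, 1), c(0, 1, 0)), calibration = 1)
#' projected_area(m)
#' @export
object_mask <- function(coords, calibration, id = 1L,
                        touches_border = FALSE, validate = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) {
    stop("object mask must contain at least one pixel", call. = FALSE)
  }
  if (ncol(coords) != 2L) {
    stop("'coords' must have two columns (row, col)", call. = FALSE)
  }
  if (any(coords < 0) || any(coords != floor(coords))) {
    stop("'coords' must be non-negative integer pixel indices", call. = FALSE)
  }
  stop_if_not_scalar_num(calibration, "calibration", 0, strict = TRUE)
  storage.mode(coords) <- "integer"
  dimnames(coords) <- list(NULL, c("row", "col"))
  m <- structure(
    list(
      id = as.integer(id), coords = coords, calibration = calibration,
      touches_border = isTRUE(touches_border)
    ),
    class = "object_mask"
  )
  if (validate && !mask_is_connected(m)) {
    stop("object mask is not 8-connected", call. = FALSE)
  }
  m
}

#' @export
print.object_mask <- function(x, ...) {
  cat(sprintf(
    "<object_mask> id %d: %d px @ %.4g um/px (A = %.4g um^2)%s\n",
    x$id, nrow(x$coords), x$calibration, projected_area(x),
    if (x$touches_border) ", touches border" else ""
  ))
  invisible(x)
}

#' Number of pixels in a mask
#' @param mask An [object_mask].
#' @return Integer pixel count.
#' @export
n_pixels <- function(mask) {
  stopifnot(inherits(mask, "object_mask"))
  nrow(mask$coords)
}

# logical bounding-box matrix of the mask plus origin offset
mask_bbox_matrix <- function(mask) {
  rc <- mask$coords
  r0 <- min(rc[, 1])
  c0 <- min(rc[, 2])
  m <- matrix(FALSE, max(rc[, 1]) - r0 + 1L, max(rc[, 2]) - c0 + 1L)
  m[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
  list(m = m, origin = c(r0, c0))
}

mask_is_connected <- function(mask) {
  bb <- mask_bbox_matrix(mask)
  max(label_components_cpp(bb$m, 8L)) == 1L
}

# pixels with at least one missing 4-neighbour (object boundary)
mask_boundary <- function(mask) {
  bb <- mask_bbox_matrix(mask)
  m <- bb$m
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  idx <- which(m & !inner, arr.ind = TRUE)
  cbind(idx[, 1] - 1L + bb$origin[1], idx[, 2] - 1L + bb$origin[2])
}

# convex hull (closed polygon, hull vertex coordinates in pixel-corner
# continuous space) of the union of the mask's pixel squares
mask_hull <- function(mask) {
  b <- mask_boundary(mask)
  pts <- rbind(
    b,
    cbind(b[, 1] + 1L, b[, 2]),
    cbind(b[, 1], b[, 2] + 1L),
    cbind(b[, 1] + 1L, b[, 2] + 1L)
  )
  pts <- unique(pts)
  h <- chull(pts)
  pts[h, , drop = FALSE]
}

# shoelace area of a polygon given as an n x 2 matrix of vertices
polygon_area <- function(p) {
  n <- nrow(p)
  if (n < 3L) {
    return(0)
  }
  j <- c(2:n, 1L)
  abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
}
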