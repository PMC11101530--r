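#' Median filter
#'
#' Replaces every pixel by the exact median of its `window` x `window`
#' neighbourhood, the standard despeckling step applied before
#' segmentation of phase-contrast micrographs. Borders are handled by
#' symmetric (reflect) padding; calibration and metadata are preserved.
#'
#' @param image A [calibrated_image].
#' @param window Odd window edge length, >= 1 and <= the smaller image
#'   dimension. `window = 1` is the identity.
#' @return A filtered [calibrated_image].
#' @examples
#' img <- calibrated_image(matrix(runif(100), 10, 10), 1)
#' median_filter(img, 3)
#' @export
median_filter <- function(image, window = 3L) {
  stopifnot(inherits(image, "calibrated_image"))
  stop_if_not_scalar_num(window, "window", 1)
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    stop("'window' must be odd", call. = FALSE)
  }
  if (window > min(dim(image$pixels))) {
    stop("'window' exceeds the image dimensions", call. = FALSE)
  }
  out <- image
  if (window > 1L) {
    out$pixels <- median_filter_cpp(image$pixels, window)
  }
  out
}

#' Sobel gradient magnitude
#'
#' Gradient magnitude `sqrt(gx^2 + gy^2)` from the standard 3 x 3 Sobel
#' kernels (weights 1-2-1), with symmetric (reflect) border padding.
#' Used to pick up edge-band pixels during segmentation.
#'
#' @param image A [calibrated_image] (at least 3 x 3).
#' @return A [calibrated_image] holding the non-negative magnitude.
#' @export
sobel_magnitude <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  x <- image$pixels
  nr <- nrow(x)
  nc <- ncol(x)
  p <- x[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  s <- function(di, dj) p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  gx <- (s(0, 2) + 2 * s(1, 2) + s(2, 2)) - (s(0, 0) + 2 * s(1, 0) + s(2, 0))
  gy <- (s(2, 0) + 2 * s(2, 1) + s(2, 2)) - (s(0, 0) + 2 * s(0, 1) + s(0, 2))
  out <- image
  out$pixels <- sqrt(gx^2 + gy^2)
  out
}
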