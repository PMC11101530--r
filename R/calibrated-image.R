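#' Calibrated grayscale image
#'
#' Container for a single-channel micrograph together with its spatial
#' calibration and sampling metadata. Intensities are stored as a numeric
#' matrix (rows = image rows); values are expected in `[0, 1]` when read
#' from or written to image files.
#'
#' @param pixels Numeric matrix of intensities, at least 3 x 3, all finite.
#' @param calibration Micrometres per pixel, > 0.
#' @param time_h Sampling time in hours.
#' @param talc_g_per_l Talc microparticle concentration of the run, g/L.
#' @param id Image identifier string.
#'
#' @return An object of class `calibrated_image`: a list with elements
#'   `pixels`, `calibration`, `time_h`, `talc_g_per_l`, `id`.
#' @examples
#' img <- calibrated_image(matrix(0.5, 10, 10), calibration = 0.65)
#' img
#' @export
calibrated_image <- function(pixels, calibration, time_h = NA_real_,
                             talc_g_per_l = NA_real_, id = "img") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop("image must be at least 3 x 3 pixels", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("image contains non-finite intensities", call. = FALSE)
  }
  stop_if_not_scalar_num(calibration, "calibration", 0, strict = TRUE)
  structure(
    list(
      pixels = pixels, calibration = calibration,
      time_h = time_h, talc_g_per_l = talc_g_per_l, id = as.character(id)
    ),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf(
    "<calibrated_image> '%s': %d x %d px @ %.4g um/px, t = %s h, talc = %s g/L\n",
    x$id, nrow(x$pixels), ncol(x$pixels), x$calibration,
    format(x$time_h), format(x$talc_g_per_l)
  ))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Read a grayscale image from TIFF or PNG
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG file into a
#' [calibrated_image]. Multi-channel images are averaged to one channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @inheritParams calibrated_image
#' @return A [calibrated_image] with intensities in `[0, 1]`.
#' @export
read_image <- function(path, calibration, time_h = NA_real_,
                       talc_g_per_l = NA_real_, id = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 3L) {
    px <- apply(px, c(1, 2), mean)
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  calibrated_image(px, calibration, time_h, talc_g_per_l, id)
}

#' Write a calibrated image to disk
#'
#' Writes intensities (clipped to `[0, 1]`) as 16-bit grayscale TIFF or
#' 8-bit PNG, chosen from the file extension.
#'
#' @param image A [calibrated_image].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  px[] <- pmin(1, pmax(0, px))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    png = png::writePNG(px, path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write segmented objects as a labeled-mask TIFF
#'
#' Encodes a segmentation as a 16-bit label image: 0 = background, k =
#' pixels of the k-th object mask.
#'
#' @param masks List of [object_mask] objects (as returned by
#'   [segment_objects()]).
#' @param dim Integer vector `c(rows, cols)` of the source image.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_labeled_masks <- function(masks, dim, path) {
  lab <- matrix(0L, dim[1], dim[2])
  for (m in masks) {
    lab[m$coords + 1L] <- m$id
  }
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a labeled-mask TIFF back into object masks
#'
#' Inverse of [write_labeled_masks()].
#'
#' @param path Path to a labeled 16-bit TIFF.
#' @param calibration Micrometres per pixel of the source image.
#' @return A list of [object_mask] objects, ordered by label.
#' @export
read_labeled_masks <- function(path, calibration) {
  lab <- round(tiff::readTIFF(path) * 65535)
  ids <- sort(unique(lab[lab > 0]))
  nr <- nrow(lab)
  nc <- ncol(lab)
  lapply(ids, function(k) {
    idx <- which(lab == k)
    rows <- (idx - 1L) %% nr
    cols <- (idx - 1L) %/% nr
    object_mask(
      cbind(rows, cols),
      calibration = calibration, id = k,
      touches_border = any(rows == 0L | cols == 0L |
        rows == nr - 1L | cols == nc - 1L)
    )
  })
}
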