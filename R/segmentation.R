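#' Segmentation configuration
#'
#' Parameters of the image-to-objects pipeline. Defaults implement the
#' automatic procedure: 3 x 3 median filter, Otsu-style bimodal threshold
#' on the filtered intensity (dark objects on a bright background),
#' Sobel edge-band refinement, hole filling, removal of objects below
#' 20 um^2 and exclusion of border-touching objects. Raise
#' `min_area_um2` to 100 to also discard ~10 um talc microparticle
#' distractors (a 10 um disk projects ~78.5 um^2).
#'
#' @param median_window Odd median-filter window, >= 1 (1 disables).
#' @param threshold `"otsu"` for the automatic bimodal threshold, or a
#'   fixed numeric intensity.
#' @param min_area_um2 Minimum object area kept, in um^2.
#' @param fill_holes Fill enclosed background holes inside objects.
#' @param border `"exclude"` drops border-touching objects, `"flag"`
#'   keeps them with `touches_border = TRUE`.
#' @param polarity `"dark_on_bright"` (phase-contrast-like default) or
#'   `"bright_on_dark"`.
#' @param sobel_refine Include edge-band pixels (high Sobel magnitude,
#'   intensity between the threshold and the background level) that are
#'   8-contiguous with a thresholded region.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(median_window = 3L,
                                threshold = "otsu",
                                min_area_um2 = 20,
                                fill_holes = TRUE,
                                border = c("exclude", "flag"),
                                polarity = c("dark_on_bright", "bright_on_dark"),
                                sobel_refine = TRUE) {
  stop_if_not_scalar_num(median_window, "median_window", 1)
  if (as.integer(median_window) %% 2L == 0L) {
    stop("'median_window' must be odd", call. = FALSE)
  }
  if (!(identical(threshold, "otsu") || is.numeric(threshold))) {
    stop("'threshold' must be \"otsu\" or a numeric value", call. = FALSE)
  }
  stop_if_not_scalar_num(min_area_um2, "min_area_um2", 0)
  structure(
    list(
      median_window = as.integer(median_window),
      threshold = threshold,
      min_area_um2 = min_area_um2,
      fill_holes = isTRUE(fill_holes),
      border = match.arg(border),
      polarity = match.arg(polarity),
      sobel_refine = isTRUE(sobel_refine)
    ),
    class = "segmentation_config"
  )
}

# fill background holes: background components (4-connected) that do not
# touch the image border are enclosed by foreground
fill_holes_binary <- function(fg) {
  bglab <- label_components_cpp(!fg, 4L)
  nr <- nrow(fg)
  nc <- ncol(fg)
  border_labs <- unique(c(
    bglab[1, ], bglab[nr, ], bglab[, 1], bglab[, nc]
  ))
  border_labs <- border_labs[border_labs > 0]
  hole <- bglab > 0 & !(bglab %in% border_labs)
  fg | matrix(hole, nr, nc)
}

#' Segment a calibrated image into object masks
#'
#' Runs the segmentation pipeline: median filter, polarity-aware
#' threshold of the filtered intensity, optional Sobel edge-band
#' refinement of object boundaries, optional hole filling, 8-connected
#' labeling, area filtering and the border policy. Masks are returned
#' sorted by decreasing area and are pairwise disjoint; a blank or
#' uniform image yields an empty list.
#'
#' @param image A [calibrated_image].
#' @param config A [segmentation_config()].
#' @return List of [object_mask] objects (possibly empty), ids `1..k` in
#'   order of decreasing pixel count.
#' @examples
#' sc <- scene_spec(n_pellet = 1, n_clump = 2, noise_sd = 0, seed = 1)
#' scn <- make_scene(sc)
#' masks <- segment_objects(scn$image, segmentation_config())
#' length(masks)
#' @export
segment_objects <- function(image, config = segmentation_config()) {
  stopifnot(inherits(image, "calibrated_image"))
  stopifnot(inherits(config, "segmentation_config"))
  filt <- median_filter(image, config$median_window)
  x <- filt$pixels
  # orient so that foreground is always "below threshold" on v
  v <- if (config$polarity == "dark_on_bright") x else -x
  if (identical(config$threshold, "otsu")) {
    thr <- otsu_threshold(v)
    if (is.na(thr)) {
      return(list())
    }
  } else {
    thr <- if (config$polarity == "dark_on_bright") {
      config$threshold
    } else {
      -config$threshold
    }
  }
  fg <- v < thr
  if (!any(fg)) {
    return(list())
  }
  if (config$sobel_refine) {
    g <- sobel_magnitude(filt)$pixels
    gthr <- otsu_threshold(g)
    if (!is.na(gthr)) {
      bg_level <- median(v[!fg])
      relaxed <- (thr + bg_level) / 2
      cand <- !fg & g > gthr & v < relaxed
      if (any(cand)) {
        lab <- label_components_cpp(fg | cand, 8L)
        keep <- unique(lab[fg])
        fg <- matrix(lab %in% keep & lab > 0, nrow(x), ncol(x))
      }
    }
  }
  if (config$fill_holes) {
    fg <- fill_holes_binary(fg)
  }
  lab <- label_components_cpp(fg, 8L)
  k <- max(lab)
  if (k == 0L) {
    return(list())
  }
  min_px <- config$min_area_um2 / image$calibration^2
  nr <- nrow(lab)
  nc <- ncol(lab)
  sizes <- tabulate(lab[lab > 0], k)
  on_border <- logical(k)
  bl <- c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc])
  on_border[unique(bl[bl > 0])] <- TRUE
  keep <- which(sizes >= min_px &
    (config$border == "flag" | !on_border))
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  masks <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i])
    masks[[i]] <- object_mask(
      cbind((idx - 1L) %% nr, (idx - 1L) %/% nr),
      calibration = image$calibration, id = i,
      touches_border = on_border[keep[i]]
    )
  }
  masks
}

#' Export segmented masks as a per-image object table
#'
#' @param masks List of [object_mask] objects.
#' @param image_id Image identifier recorded in every row.
#' @return A data.frame with columns `image_id`, `object_id`,
#'   `n_pixels`, `touches_border`.
#' @export
masks_table <- function(masks, image_id = "img") {
  data.frame(
    image_id = rep(as.character(image_id), length(masks)),
    object_id = vapply(masks, function(m) m$id, integer(1)),
    n_pixels = vapply(masks, n_pixels, integer(1)),
    touches_border = vapply(masks, function(m) m$touches_border, logical(1))
  )
}
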