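#' Scene specification for the synthetic image generator
#'
#' Describes one synthetic micrograph: image geometry, sampling
#' metadata, how many objects of each morphological class to draw, the
#' per-class shape parameter ranges, optional ~10 um talc microparticle
#' distractors, and the noise model (additive Gaussian on a bright
#' background, objects rendered dark, phase-contrast-like polarity).
#'
#' Default shape ranges emulate the morphological groups observed in
#' talc-amended *S. rimosus* cultures: pellets with projected areas in
#' the 10^4-10^6 um^2 range, clumps/free hyphae below ~164 um^2, and
#' small round spores at inoculation.
#'
#' @param image_size Integer `c(rows, cols)` in pixels (scalar = square).
#' @param calibration Micrometres per pixel, > 0.
#' @param time_h Sampling time, h.
#' @param talc_g_per_l Talc concentration of the emulated run, g/L.
#' @param n_spore,n_pellet,n_clump,n_talc Object counts per class, >= 0.
#' @param pellet_radius_um Range of pellet base radii, um.
#' @param pellet_roughness Range of boundary-roughness amplitudes,
#'   `[0, 1)`.
#' @param pellet_aspect Range of pellet target aspect ratios, >= 1.
#' @param clump_length_um,clump_width_um Ranges of filament path length
#'   and width, um.
#' @param branch_probability Per-site branching probability of clump
#'   filaments, `[0, 1]`.
#' @param spore_radius_um,spore_aspect Ranges for the spore class.
#' @param talc_diameter_um Talc distractor diameter (default 10 um, the
#'   nominal mean particle size of -350 mesh talc).
#' @param background Background intensity in `[0, 1]`.
#' @param intensities Named list of per-class foreground intensities.
#' @param noise_sd Additive Gaussian noise SD, >= 0 (intensities are
#'   clipped to `[0, 1]` afterwards).
#' @param seed Integer seed; the scene is a pure function of the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 768L,
                       calibration = 1,
                       time_h = 24,
                       talc_g_per_l = 0,
                       n_spore = 0L, n_pellet = 2L, n_clump = 6L,
                       n_talc = 0L,
                       pellet_radius_um = c(60, 120),
                       pellet_roughness = c(0.05, 0.3),
                       pellet_aspect = c(1, 1.6),
                       clump_length_um = c(8, 30),
                       clump_width_um = c(1.5, 2.5),
                       branch_probability = 0.3,
                       spore_radius_um = c(3, 8),
                       spore_aspect = c(1, 1.3),
                       talc_diameter_um = 10,
                       background = 0.85,
                       intensities = list(
                         spore = 0.35, pellet = 0.25,
                         clump_hyphae = 0.3, talc = 0.05
                       ),
                       noise_sd = 0.02,
                       seed = 1L) {
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  if (any(image_size < 3L)) {
    stop("'image_size' must be at least 3 x 3", call. = FALSE)
  }
  stop_if_not_scalar_num(calibration, "calibration", 0, strict = TRUE)
  counts <- c(n_spore, n_pellet, n_clump, n_talc)
  if (any(counts < 0)) {
    stop("object counts must be >= 0", call. = FALSE)
  }
  if (min(pellet_aspect) < 1 || min(spore_aspect) < 1) {
    stop("aspect ratios must be >= 1", call. = FALSE)
  }
  if (min(pellet_roughness) < 0 || max(pellet_roughness) >= 1) {
    stop("'pellet_roughness' must be within [0, 1)", call. = FALSE)
  }
  if (branch_probability < 0 || branch_probability > 1) {
    stop("'branch_probability' must be in [0, 1]", call. = FALSE)
  }
  stop_if_not_scalar_num(noise_sd, "noise_sd", 0)
  structure(
    list(
      image_size = image_size, calibration = calibration,
      time_h = time_h, talc_g_per_l = talc_g_per_l,
      n_spore = as.integer(n_spore), n_pellet = as.integer(n_pellet),
      n_clump = as.integer(n_clump), n_talc = as.integer(n_talc),
      pellet_radius_um = range(pellet_radius_um),
      pellet_roughness = range(pellet_roughness),
      pellet_aspect = range(pellet_aspect),
      clump_length_um = range(clump_length_um),
      clump_width_um = range(clump_width_um),
      branch_probability = branch_probability,
      spore_radius_um = range(spore_radius_um),
      spore_aspect = range(spore_aspect),
      talc_diameter_um = talc_diameter_um,
      background = background, intensities = intensities,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

runif1 <- function(r) runif(1, r[1], r[2])

#' Render a synthetic scene with per-object ground truth
#'
#' Draws the requested objects (pellets, clumps/hyphae, spores, talc
#' distractors) at non-overlapping positions away from the image border,
#' renders them dark on a bright background, adds Gaussian noise and
#' clips to `[0, 1]`. The returned ground truth lists every object with
#' its class, analytic true area, true aspect ratio and centroid.
#' Identical spec (including seed) gives bit-identical output.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `synthetic_scene` with elements `image`
#'   ([calibrated_image]), `truth` (data.frame: `object_id`, `class`,
#'   `true_area_um2`, `true_aspect`, `centroid_row`, `centroid_col`),
#'   and `masks` (list of placed [object_mask]s, same order).
#' @examples
#' scn <- make_scene(scene_spec(n_pellet = 1, n_clump = 3, seed = 42))
#' scn$truth
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  cal <- spec$calibration
  with_seed(spec$seed, {
    plan <- c(
      rep("pellet", spec$n_pellet),
      rep("clump_hyphae", spec$n_clump),
      rep("spore", spec$n_spore),
      rep("talc", spec$n_talc)
    )
    masks <- list()
    boxes <- matrix(numeric(0), ncol = 4) # r0, r1, c0, c1 (expanded)
    truth <- list()
    margin <- 3L
    for (i in seq_along(plan)) {
      cls <- plan[i]
      m <- switch(cls,
        pellet = make_pellet_mask(
          runif1(spec$pellet_radius_um), runif1(spec$pellet_roughness),
          runif1(spec$pellet_aspect), cal,
          seed = sample.int(2e9, 1), angle = runif(1, 0, pi)
        ),
        clump_hyphae = make_filament_mask(
          runif1(spec$clump_length_um), runif1(spec$clump_width_um),
          spec$branch_probability, cal,
          seed = sample.int(2e9, 1), angle = runif(1, 0, pi)
        ),
        spore = make_pellet_mask(
          runif1(spec$spore_radius_um), 0,
          runif1(spec$spore_aspect), cal,
          seed = sample.int(2e9, 1), angle = runif(1, 0, pi)
        ),
        talc = make_pellet_mask(
          spec$talc_diameter_um / 2, 0, 1, cal,
          seed = sample.int(2e9, 1)
        )
      )
      h <- max(m$coords[, 1]) + 1L
      w <- max(m$coords[, 2]) + 1L
      if (h + 2 * margin >= nr || w + 2 * margin >= nc) {
        stop(sprintf(
          "cannot fit %s object within the image (placed %d of %d)",
          cls, i - 1L, length(plan)
        ), call. = FALSE)
      }
      placed <- FALSE
      for (try in seq_len(200L)) {
        r0 <- sample.int(nr - h - 2L * margin, 1L) + margin
        c0 <- sample.int(nc - w - 2L * margin, 1L) + margin
        box <- c(r0 - margin, r0 + h + margin, c0 - margin, c0 + w + margin)
        clash <- nrow(boxes) > 0 && any(
          boxes[, 1] <= box[2] & boxes[, 2] >= box[1] &
            boxes[, 3] <= box[4] & boxes[, 4] >= box[3]
        )
        if (!clash) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(
          "could not place %s object without overlap (placed %d of %d)",
          cls, i - 1L, length(plan)
        ), call. = FALSE)
      }
      boxes <- rbind(boxes, box)
      pm <- object_mask(
        cbind(m$coords[, 1] + r0, m$coords[, 2] + c0),
        calibration = cal, id = i
      )
      attributes(pm)[c("true_area_um2", "true_aspect")] <-
        attributes(m)[c("true_area_um2", "true_aspect")]
      masks[[i]] <- pm
      truth[[i]] <- data.frame(
        object_id = i, class = cls,
        true_area_um2 = attr(m, "true_area_um2"),
        true_aspect = attr(m, "true_aspect"),
        centroid_row = mean(pm$coords[, 1]),
        centroid_col = mean(pm$coords[, 2])
      )
    }
    img <- matrix(spec$background, nr, nc)
    for (i in seq_along(masks)) {
      img[masks[[i]]$coords + 1L] <- spec$intensities[[plan[i]]]
    }
    if (spec$noise_sd > 0) {
      img <- img + rnorm(length(img), 0, spec$noise_sd)
      img <- pmin(1, pmax(0, img))
      img <- matrix(img, nr, nc)
    }
    image <- calibrated_image(
      img, cal, spec$time_h, spec$talc_g_per_l,
      id = sprintf(
        "scene_t%g_talc%g_seed%d", spec$time_h, spec$talc_g_per_l,
        spec$seed
      )
    )
    structure(
      list(
        image = image,
        truth = if (length(truth)) {
          do.call(rbind, truth)
        } else {
          data.frame(
            object_id = integer(), class = character(),
            true_area_um2 = numeric(), true_aspect = numeric(),
            centroid_row = numeric(), centroid_col = numeric()
          )
        },
        masks = masks
      ),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d x %d px, %d objects (%s)\n",
    nrow(x$image$pixels), ncol(x$image$pixels), nrow(x$truth),
    paste(names(table(x$truth$class)), table(x$truth$class),
      sep = ":", collapse = ", "
    )
  ))
  invisible(x)
}
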