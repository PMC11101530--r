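#' Pipeline configuration
#'
#' Assembles the end-to-end analysis configuration: which stages run
#' (`simulate`, `segment`, `measure`, `metabolics`), where inputs come
#' from when simulation is off, segmentation and classification
#' parameters, the significance level, the spline mode and the master
#' seed from which every stage derives its own seed. All defaults give
#' a self-contained demonstration run on synthetic data.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed.
#' @param stages Character vector of enabled stages, in pipeline order.
#' @param image_dir Directory of input images when `simulate` is off.
#'   Images must be named `<id>_t<time>_talc<conc>.tif/png`.
#' @param timeseries_csv Replicate time-series CSV when `simulate` is
#'   off.
#' @param conditions,times Talc concentrations (g/L) and sampling times
#'   (h) simulated per scene grid.
#' @param scene Named list of [scene_spec()] overrides applied to every
#'   simulated scene.
#' @param timeseries Named list of [timeseries_spec()] overrides.
#' @param segmentation A [segmentation_config()].
#' @param thresholds A [morpho_thresholds()].
#' @param alpha Significance level used throughout.
#' @param spline_method Spline mode for uptake rates (`"cubic"`,
#'   `"natural"` or `"smooth"`).
#' @param calibration Micrometres per pixel assumed for read images.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mycomorph_run_"),
                            seed = 1L,
                            stages = c(
                              "simulate", "segment", "measure",
                              "metabolics"
                            ),
                            image_dir = NULL,
                            timeseries_csv = NULL,
                            conditions = c(0, 5),
                            times = c(0, 24, 96),
                            scene = list(),
                            timeseries = list(),
                            segmentation = segmentation_config(),
                            thresholds = morpho_thresholds(),
                            alpha = 0.05,
                            spline_method = "cubic",
                            calibration = 1) {
  stages <- match.arg(stages,
    c("simulate", "segment", "measure", "metabolics"),
    several.ok = TRUE
  )
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), stages = stages,
      image_dir = image_dir, timeseries_csv = timeseries_csv,
      conditions = conditions, times = times,
      scene = scene, timeseries = timeseries,
      segmentation = segmentation, thresholds = thresholds,
      alpha = alpha, spline_method = spline_method,
      calibration = calibration
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration as YAML
#'
#' Serialises the scalar and list-valued fields of a
#' [pipeline_config()] to a structured key-value file and back.
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  plain <- intersect(names(y), c(
    "out_dir", "seed", "stages", "image_dir", "timeseries_csv",
    "conditions", "times", "scene", "timeseries", "alpha",
    "spline_method", "calibration"
  ))
  cfg[plain] <- y[plain]
  if (!is.null(y$segmentation)) {
    cfg$segmentation <- do.call(segmentation_config, y$segmentation)
  }
  if (!is.null(y$thresholds)) {
    cfg$thresholds <- do.call(morpho_thresholds, y$thresholds)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$segmentation <- unclass(y$segmentation)
  y$thresholds <- unclass(y$thresholds)
  yaml::write_yaml(y, path)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = con, append = TRUE)
  invisible(msg)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the enabled stages in order: `simulate` (synthetic scenes
#' per condition x time plus a replicate time series), `segment`
#' (median filter, threshold, labeling), `measure` (shape descriptors,
#' classification, group summaries) and `metabolics` (enhancement
#' factors and glucose uptake rates). Writes, under `out_dir`: images
#' and labeled-mask TIFFs, ground-truth, per-object, group-summary, EF
#' and uptake CSVs, and a run log echoing the configuration, seeds and
#' per-stage object counts. Identical configuration and seed give
#' byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` (invisibly): `objects`,
#'   `summary`, `ef`, `uptake`, `truth`, `files`, `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(
#'   conditions = 0, times = 24,
#'   scene = list(image_size = 256, n_pellet = 1, n_clump = 2,
#'     pellet_radius_um = c(30, 40))
#' )
#' rep <- run_pipeline(cfg)
#' rep
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  # pre-flight validation before any stage runs
  if (!("simulate" %in% stages)) {
    if ("segment" %in% stages &&
      (is.null(config$image_dir) || !dir.exists(config$image_dir))) {
      stop("pre-flight: stage 'segment' enabled but 'image_dir' is missing",
        call. = FALSE
      )
    }
    if ("metabolics" %in% stages &&
      (is.null(config$timeseries_csv) ||
        !file.exists(config$timeseries_csv))) {
      stop("pre-flight: stage 'metabolics' enabled but 'timeseries_csv' is missing",
        call. = FALSE
      )
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  pipeline_log(
    log_path, "mycomorph %s | R %s | run at %s",
    as.character(packageVersion("mycomorph")),
    paste(R.version$major, R.version$minor, sep = "."),
    format(Sys.time())
  )
  pipeline_log(log_path, "master seed: %d", config$seed)
  cfg_path <- file.path(config$out_dir, "config.yml")
  write_pipeline_config(config, cfg_path)
  pipeline_log(log_path, "config echoed to %s", basename(cfg_path))

  files <- character(0)
  images <- list()
  truth_all <- NULL
  ts <- NULL

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      k <- 0L
      for (cond in config$conditions) {
        for (t in config$times) {
          k <- k + 1L
          base <- list(
            time_h = t, talc_g_per_l = cond,
            calibration = config$calibration,
            seed = derive_seed(config$seed, k)
          )
          if (t == 0) {
            base <- c(base, list(n_spore = 25L, n_pellet = 0L, n_clump = 0L))
          }
          # user scene overrides apply except to the per-scene grid
          # fields (time, condition, seed) and the 0 h spore-only counts
          sp <- do.call(
            scene_spec,
            modifyList(as.list(config$scene), base)
          )
          scn <- make_scene(sp)
          img_path <- file.path(
            config$out_dir, paste0(scn$image$id, ".tif")
          )
          write_image(scn$image, img_path)
          tr <- scn$truth
          if (nrow(tr)) {
            tr$image_id <- scn$image$id
            tr$time_h <- t
            tr$talc_g_per_L <- cond
          }
          truth_all <- rbind(truth_all, tr)
          images[[scn$image$id]] <- scn$image
          files <- c(files, img_path)
          pipeline_log(
            log_path, "simulate: %s (%d objects)",
            scn$image$id, nrow(scn$truth)
          )
        }
      }
      if (!is.null(truth_all)) {
        tp <- file.path(config$out_dir, "ground_truth.csv")
        write.csv(truth_all, tp, row.names = FALSE)
        files <- c(files, tp)
      }
      ts_args <- modifyList(
        list(conditions = config$conditions),
        as.list(config$timeseries)
      )
      ts_args$seed <- derive_seed(config$seed, 900L)
      tss <- do.call(timeseries_spec, ts_args)
      ts <- make_timeseries(tss)
      tsp <- file.path(config$out_dir, "timeseries.csv")
      write_timeseries_csv(ts, tsp)
      files <- c(files, tsp)
      pipeline_log(log_path, "simulate: time series %d rows", nrow(ts))
    })
  } else {
    if ("segment" %in% stages) {
      paths <- list.files(config$image_dir,
        pattern = "\\.(tif|tiff|png)$",
        full.names = TRUE, ignore.case = TRUE
      )
      for (p in paths) {
        id <- tools::file_path_sans_ext(basename(p))
        meta <- regmatches(
          id, regexec("_t([0-9.]+)_talc([0-9.]+)", id)
        )[[1]]
        t <- if (length(meta) == 3) as.numeric(meta[2]) else NA_real_
        cond <- if (length(meta) == 3) as.numeric(meta[3]) else NA_real_
        images[[id]] <- read_image(p, config$calibration, t, cond, id)
      }
    }
    if ("metabolics" %in% stages) {
      ts <- read_timeseries_csv(config$timeseries_csv)
    }
  }

  records <- NULL
  if ("segment" %in% stages) {
    run_stage("segment", {
      obj_rows <- NULL
      for (img in images) {
        masks <- segment_objects(img, config$segmentation)
        lp <- file.path(config$out_dir, paste0(img$id, "_labels.tif"))
        write_labeled_masks(masks, dim(img), lp)
        files <- c(files, lp)
        obj_rows <- rbind(obj_rows, masks_table(masks, img$id))
        pipeline_log(
          log_path, "segment: %s -> %d objects", img$id, length(masks)
        )
        if ("measure" %in% stages) {
          rec <- measure_objects(masks, img$time_h, img$talc_g_per_l, img$id)
          records <- rbind(records, rec)
        }
      }
      if (!is.null(obj_rows)) {
        op <- file.path(config$out_dir, "segmented_objects.csv")
        write.csv(obj_rows, op, row.names = FALSE)
        files <- c(files, op)
      }
    })
  }

  summary_df <- NULL
  if ("measure" %in% stages && !is.null(records) && nrow(records)) {
    run_stage("measure", {
      records <- classify_objects(records, config$thresholds)
      rp <- file.path(config$out_dir, "morphometrics.csv")
      write.csv(records, rp, row.names = FALSE)
      summary_df <- summarize_morphology(records, config$alpha)
      sp <- file.path(config$out_dir, "group_summary.csv")
      write.csv(summary_df, sp, row.names = FALSE)
      files <- c(files, rp, sp)
      pipeline_log(
        log_path, "measure: %d objects, %d summary rows",
        nrow(records), nrow(summary_df)
      )
    })
  }

  ef <- NULL
  uptake <- NULL
  if ("metabolics" %in% stages && !is.null(ts)) {
    run_stage("metabolics", {
      ef <- enhancement_table(ts, alpha = config$alpha)
      ep <- file.path(config$out_dir, "enhancement_factors.csv")
      write.csv(ef, ep, row.names = FALSE)
      uptake <- glucose_uptake_table(ts, method = config$spline_method)
      up <- file.path(config$out_dir, "glucose_uptake.csv")
      write.csv(uptake, up, row.names = FALSE)
      files <- c(files, ep, up)
      pipeline_log(
        log_path, "metabolics: %d EF rows, %d uptake rows",
        nrow(ef), nrow(uptake)
      )
    })
  }

  report <- structure(
    list(
      objects = records, summary = summary_df, ef = ef, uptake = uptake,
      truth = truth_all, files = files, config = config
    ),
    class = "pipeline_report"
  )
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  output: %s\n", x$config$out_dir))
  if (!is.null(x$objects)) {
    cat(sprintf(
      "  objects measured: %d (%s)\n", nrow(x$objects),
      paste(names(table(x$objects$class)), table(x$objects$class),
        sep = ":", collapse = ", "
      )
    ))
  }
  if (!is.null(x$ef)) {
    cat(sprintf("  EF rows: %d | uptake rows: %d\n",
      nrow(x$ef), nrow(x$uptake)))
  }
  cat(sprintf("  files written: %d\n", length(x$files)))
  invisible(x)
}
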