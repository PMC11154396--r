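# ------------------------------------------------------------------------
# Orchestration: validated configuration and the simulate -> preprocess ->
# detect -> score -> evaluate pipeline with structured logging.
# ------------------------------------------------------------------------

#' Pipeline configuration
#'
#' Validated bundle of every tunable constant. The defaults are the working
#' values of the scoring protocol: 256 px tiles, 65% background exclusion,
#' candidate threshold 0.1, NMS distance 12 px, match radius 8 px, FP
#' operating points \{10, 20, 50, 100, 200, 300\}, 12 px annotation boxes
#' and a 16 x 16 px lymphocyte footprint from an 8 um diameter at
#' 0.5 um/px.
#'
#' @param tile_side Tile side in pixels.
#' @param max_bg Maximum tolerated background fraction per tile.
#' @param tau Candidate retention threshold on the detection map.
#' @param nms_distance Non-maximum-suppression distance in pixels.
#' @param match_radius True-positive matching radius in pixels.
#' @param fp_targets FP/image operating points for the FROC score.
#' @param box_side Annotation bounding-box side in pixels.
#' @param resolution_um_per_px Sampling resolution.
#' @param lymphocyte_diameter_um Nominal lymphocyte equivalent diameter.
#' @param seed Integer seed driving all simulation randomness.
#' @param n_slides Number of slides to simulate when no input is given.
#' @param slide_width,slide_height Simulated slide size in pixels.
#' @param noise_sigma,blur_radius Generator corruption parameters (see
#'   [synth_params()]).
#' @param density_range Lymphocyte-rate multiplier range across simulated
#'   slides.
#' @param input_dir Existing cohort directory (`NULL` to simulate).
#' @param out_dir Output directory for all artifacts.
#' @return A validated `pipeline_config` list; the derived
#'   `lymphocyte_area` (px^2) is included.
#' @export
pipeline_config <- function(tile_side = 256,
                            max_bg = 0.65,
                            tau = 0.1,
                            nms_distance = 12,
                            match_radius = 8,
                            fp_targets = c(10, 20, 50, 100, 200, 300),
                            box_side = 12,
                            resolution_um_per_px = 0.5,
                            lymphocyte_diameter_um = 8,
                            seed = 1L,
                            n_slides = 20L,
                            slide_width = 1024L,
                            slide_height = 1024L,
                            noise_sigma = 0,
                            blur_radius = 2,
                            density_range = c(0.3, 2.5),
                            input_dir = NULL,
                            out_dir = tempfile("stromatil_run_")) {
  if (tau < 0 || tau >= 1) stop("`tau` must lie in [0, 1)", call. = FALSE)
  if (max_bg < 0 || max_bg > 1) stop("`max_bg` must lie in [0, 1]", call. = FALSE)
  if (tile_side < 1) stop("`tile_side` must be >= 1", call. = FALSE)
  if (nms_distance < 0) stop("`nms_distance` must be >= 0", call. = FALSE)
  if (match_radius < 0) stop("`match_radius` must be >= 0", call. = FALSE)
  if (any(fp_targets <= 0)) stop("`fp_targets` must be positive", call. = FALSE)
  if (box_side < 1) stop("`box_side` must be >= 1", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (n_slides < 1) stop("`n_slides` must be >= 1", call. = FALSE)
  structure(
    list(
      tile_side = tile_side, max_bg = max_bg, tau = tau,
      nms_distance = nms_distance, match_radius = match_radius,
      fp_targets = fp_targets, box_side = box_side,
      resolution_um_per_px = resolution_um_per_px,
      lymphocyte_diameter_um = lymphocyte_diameter_um,
      lymphocyte_area = lymphocyte_footprint_px2(
        lymphocyte_diameter_um, resolution_um_per_px
      ),
      seed = as.integer(seed), n_slides = as.integer(n_slides),
      slide_width = as.integer(slide_width),
      slide_height = as.integer(slide_height),
      noise_sigma = noise_sigma, blur_radius = blur_radius,
      density_range = density_range,
      input_dir = input_dir, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration (YAML)
#'
#' The file holds any subset of [pipeline_config()] fields; missing fields
#' take their defaults and the result is re-validated.
#'
#' @param path YAML file path.
#' @return `read_config()`: a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @return `write_config()`: the path, invisibly.
#' @export
write_config <- function(config, path) {
  drop <- c("lymphocyte_area") # derived
  yaml::write_yaml(unclass(config)[setdiff(names(unclass(config)), drop)], path)
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[stromatil:%s] %s", stage, paste0(...)))
}

#' Run the full TIL-scoring pipeline
#'
#' Stages: simulate (when `config$input_dir` is `NULL`), then per slide
#' preprocess (tile, background-filter), detect (threshold + NMS on the
#' detection map), score (stroma-restricted Eq.-style aggregation), and
#' finally evaluate (per-class Dice of the segmentation argmax against the
#' merged truth, FROC over slides against annotation box centers, Pearson
#' correlation of predicted vs reference TIL scores). All intermediate
#' artifacts, a metrics report (JSON + CSV) and run metadata (config,
#' fingerprint, seed) are written under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The report list: `dice_tumor`, `dice_stroma`, `dice_average`,
#'   `froc_score`, `pearson_r`, `n_slides`, `n_excluded_undefined`, plus
#'   `per_slide` (data frame) and `froc` (curve).
#' @export
run_til_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  det_dir <- file.path(config$out_dir, "detections")
  dir.create(det_dir, showWarnings = FALSE)

  if (is.null(config$input_dir)) {
    pipeline_log("simulate", "generating ", config$n_slides, " slide(s), noise_sigma=",
      config$noise_sigma)
    params <- synth_params(
      width = config$slide_width, height = config$slide_height,
      min_separation = config$nms_distance,
      noise_sigma = config$noise_sigma, blur_radius = config$blur_radius,
      seed = config$seed
    )
    cohort_dir <- file.path(config$out_dir, "cohort")
    cohort <- generate_cohort(config$n_slides, params, cohort_dir,
      density_range = config$density_range,
      tile_side = config$tile_side, max_bg = config$max_bg
    )
  } else {
    cohort_dir <- config$input_dir
    manifest <- read.csv(file.path(cohort_dir, "manifest.csv"),
      stringsAsFactors = FALSE
    )
    cohort <- list(
      dir = cohort_dir, manifest = manifest,
      scores = read_scores(file.path(cohort_dir, "til-scores.csv"))
    )
  }
  legend <- read_legend_json(file.path(cohort_dir, "legend.json"))

  n <- nrow(cohort$manifest)
  per_slide <- vector("list", n)
  froc_input <- vector("list", n)
  dice_mat <- matrix(NA_real_, n, 4,
    dimnames = list(NULL, c("tumor", "stroma", "other", "average"))
  )
  for (i in seq_len(n)) {
    row <- cohort$manifest[i, ]
    sid <- row$slide_id
    tissue_px <- read_label_raster(file.path(cohort_dir, row$tissue))
    tissue <- tissue_map(tissue_px, legend)
    seg <- read_prob_raster(file.path(cohort_dir, row$seg), bands = 3)
    det_map <- read_prob_raster(file.path(cohort_dir, row$det), bands = 1)
    coco <- read_coco(file.path(cohort_dir, row$coco))

    grid <- tile_image(tissue_px, config$tile_side)
    grid$windows$bg_fraction <- grid_background_fractions(
      tissue_px, grid,
      mode = "label", legend = legend
    )
    n_all <- nrow(grid$windows)
    grid <- filter_patches(grid, config$max_bg)
    pipeline_log("preprocess", sid, ": ", nrow(grid$windows), "/", n_all,
      " tile(s) retained")

    dets <- detect_lymphocytes(det_map, config$tau, config$nms_distance)
    pipeline_log("detect", sid, ": ", nrow(dets), " detection(s)")
    write_detections(dets, file.path(det_dir, paste0(sid, ".csv")), sid)

    stroma <- stroma_mask(seg)
    rec <- score_slide(stroma, dets,
      grid = grid, slide_id = sid,
      lymphocyte_area = config$lymphocyte_area
    )
    per_slide[[i]] <- data.frame(
      slide_id = sid,
      n_tils_in_stroma = rec$n_tils_in_stroma,
      stroma_pixels = rec$stroma_pixels,
      raw_score = rec$raw_score,
      til_score = rec$score,
      defined = rec$defined
    )
    dice_mat[i, ] <- per_class_dice(seg_argmax(seg), merge_classes(tissue))
    froc_input[[i]] <- list(detections = dets, gt = coco_centers(coco))
  }
  pred <- do.call(rbind, per_slide)
  write_scores(pred, file.path(config$out_dir, "til_scores_pred.csv"))

  pipeline_log("evaluate", "matching detections and correlating scores")
  curve <- froc_curve(froc_input, config$match_radius)
  fscore <- froc_score(curve, config$fp_targets)
  write.csv(curve, file.path(config$out_dir, "froc_curve.csv"),
    row.names = FALSE
  )

  ref <- cohort$scores[match(pred$slide_id, cohort$scores$slide_id), ]
  n_undef <- sum(is.na(pred$til_score) | is.na(ref$til_score))
  if (n_undef > 0) {
    warning(n_undef, " slide(s) with undefined score excluded from Pearson",
      call. = FALSE
    )
  }
  pr <- tryCatch(
    pearson_scores(pred$til_score, ref$til_score),
    error = function(e) {
      warning("Pearson undefined: ", conditionMessage(e), call. = FALSE)
      NA_real_
    }
  )

  report <- list(
    dice_tumor = mean(dice_mat[, "tumor"]),
    dice_stroma = mean(dice_mat[, "stroma"]),
    dice_average = mean(dice_mat[, "average"]),
    froc_score = fscore,
    pearson_r = pr,
    n_slides = n,
    n_excluded_undefined = n_undef
  )
  jsonlite::write_json(
    c(report, list(
      config_fingerprint = config_fingerprint(config),
      seed = config$seed
    )),
    file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  write.csv(as.data.frame(report), file.path(config$out_dir, "report.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
      fingerprint = config_fingerprint(config)
    ),
    file.path(config$out_dir, "run_meta.json"),
    auto_unbox = TRUE, digits = NA
  )
  pipeline_log("done", sprintf(
    "%d slide(s) in %.1fs | dice_avg=%.3f froc=%.3f pearson=%.3f",
    n, as.numeric(difftime(Sys.time(), t0, units = "secs")),
    report$dice_average, report$froc_score,
    ifelse(is.na(report$pearson_r), NaN, report$pearson_r)
  ))
  c(report, list(per_slide = pred, froc = curve))
}
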