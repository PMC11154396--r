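# ------------------------------------------------------------------------
# Synthetic slide generator: tissue blob fields, stroma-concentrated
# lymphocyte point processes, corrupted probability maps, COCO annotations
# and cohorts with reference TIL scores. Every output is a pure function of
# (params, seed).
# ------------------------------------------------------------------------

# Fixed band order used when thresholding the smooth field into classes:
# tumor core -> stromal rim -> parenchyma/rest -> background, so adjacency
# between tumor and its stroma mimics real sections.
.band_order <- c(
  "invasive_tumor", "in_situ_tumor", "tumor_assoc_stroma",
  "inflamed_stroma", "healthy_glands", "necrosis", "rest", "background"
)

#' Parameters for the synthetic slide generator
#'
#' @param width,height Raster size in pixels.
#' @param class_fractions Named numeric vector of target area fractions per
#'   fine tissue class (names from [fine_class_legend()]); non-negative and
#'   summing to 1.
#' @param blob_scale Characteristic tissue-region size in pixels (Gaussian
#'   correlation length of the underlying random field).
#' @param lympho_rate Named numeric vector of expected lymphocytes per pixel
#'   for each fine class; highest in inflamed stroma, reflecting TILs as
#'   lymphocytes within the stromal compartment.
#' @param min_separation Minimum pairwise distance between generated points
#'   (pixels); enforced by hard-core thinning.
#' @param noise_sigma Standard deviation of the Gaussian corruption applied
#'   to the rendered probability maps (dimensionless, >= 0). 0 gives maps
#'   that reproduce the ground truth exactly.
#' @param blur_radius Gaussian radius (sd, pixels) of the detection-map bump
#'   rendered around each lymphocyte; 0 renders single hot pixels. Also sets
#'   the correlation length (3 x `blur_radius`) of the detection-map noise
#'   field.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated list of class `synth_params`.
#' @export
#' @examples
#' p <- synth_params(width = 256, height = 256, seed = 7)
#' tm <- generate_tissue_map(p)
synth_params <- function(width = 1024,
                         height = 1024,
                         class_fractions = c(
                           invasive_tumor = 0.25,
                           in_situ_tumor = 0.03,
                           tumor_assoc_stroma = 0.20,
                           inflamed_stroma = 0.20,
                           healthy_glands = 0.05,
                           necrosis = 0.02,
                           rest = 0.10,
                           background = 0.15
                         ),
                         blob_scale = 24,
                         lympho_rate = c(
                           background = 0,
                           invasive_tumor = 1e-4,
                           tumor_assoc_stroma = 5e-4,
                           in_situ_tumor = 5e-5,
                           healthy_glands = 5e-5,
                           necrosis = 0,
                           inflamed_stroma = 1.5e-3,
                           rest = 5e-5
                         ),
                         min_separation = 12,
                         noise_sigma = 0,
                         blur_radius = 2,
                         seed = 1L) {
  if (length(width) != 1 || length(height) != 1 || width < 1 || height < 1) {
    stop("`width` and `height` must be positive scalars", call. = FALSE)
  }
  legend <- fine_class_legend()
  if (is.null(names(class_fractions)) ||
    !all(names(class_fractions) %in% names(legend))) {
    stop("`class_fractions` must be named with fine class names", call. = FALSE)
  }
  if (any(class_fractions < 0)) {
    stop("`class_fractions` must be non-negative", call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("`class_fractions` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (is.null(names(lympho_rate)) ||
    !all(names(lympho_rate) %in% names(legend))) {
    stop("`lympho_rate` must be named with fine class names", call. = FALSE)
  }
  if (any(lympho_rate < 0)) stop("`lympho_rate` must be >= 0", call. = FALSE)
  if (min_separation < 0) stop("`min_separation` must be >= 0", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (blur_radius < 0) stop("`blur_radius` must be >= 0", call. = FALSE)
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      class_fractions = class_fractions, blob_scale = blob_scale,
      lympho_rate = lympho_rate, min_separation = min_separation,
      noise_sigma = noise_sigma, blur_radius = blur_radius,
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

#' Generate a fine tissue label map
#'
#' Draws a Gaussian random field with correlation length `blob_scale`,
#' smooths it spectrally and slices it at the rank quantiles given by the
#' cumulative class fractions. Regions are spatially contiguous level-set
#' bands and empirical class fractions match the request to within rounding
#' of one rank unit.
#'
#' @param params A [synth_params()] object.
#' @return A [tissue_map()] over the eight fine classes.
#' @export
generate_tissue_map <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  legend <- fine_class_legend()
  h <- params$height
  w <- params$width
  n <- h * w
  field <- withr::with_seed(derive_seed(params$seed, 1L), {
    gaussian_smooth_fft(matrix(rnorm(n), h, w), params$blob_scale)
  })
  classes <- intersect(.band_order, names(params$class_fractions))
  fr <- params$class_fractions[classes]
  bounds <- round_half_up(cumsum(fr) * n)
  bounds[length(bounds)] <- n
  counts <- diff(c(0, bounds))
  # rank r pixel gets the class whose cumulative-count interval contains r
  assign_by_rank <- rep.int(seq_along(classes), counts)
  ranks <- rank(field, ties.method = "first")
  pix <- matrix(legend[classes][assign_by_rank[ranks]], h, w)
  tissue_map(pix, legend)
}

#' Sample lymphocyte points on a tissue map
#'
#' Homogeneous Poisson process per fine class (intensity
#' `lympho_rate[class]` points per pixel) with hard-core thinning: points
#' are drawn in a random order and a point is kept only if it lies at least
#' `min_separation` pixels from every earlier kept point.
#'
#' @param tissue A [tissue_map()].
#' @param params A [synth_params()] whose dimensions match `tissue`.
#' @return A data frame with integer columns `x`, `y` (0-based pixel
#'   coordinates).
#' @export
sample_lymphocyte_points <- function(tissue, params) {
  stopifnot(inherits(tissue, "tissue_map"), inherits(params, "synth_params"))
  if (!identical(dim(tissue$pixels), c(params$height, params$width))) {
    stop("`tissue` and `params` dimensions differ", call. = FALSE)
  }
  legend <- tissue$legend
  present_codes <- sort(unique(as.vector(tissue$pixels)))
  present <- names(legend)[match(present_codes, legend)]
  missing_rate <- setdiff(present, names(params$lympho_rate))
  if (length(missing_rate) > 0) {
    stop("`lympho_rate` missing class(es): ",
      paste(missing_rate, collapse = ", "),
      call. = FALSE
    )
  }
  h <- nrow(tissue$pixels)
  withr::with_seed(derive_seed(params$seed, 2L), {
    xs <- integer(0)
    ys <- integer(0)
    for (cls in present) {
      rate <- params$lympho_rate[[cls]]
      if (rate <= 0) next
      cells <- which(tissue$pixels == legend[[cls]])
      n_draw <- rpois(1L, rate * length(cells))
      if (n_draw == 0) next
      draw <- sample(cells, n_draw, replace = TRUE)
      ys <- c(ys, (draw - 1L) %% h)
      xs <- c(xs, (draw - 1L) %/% h)
    }
    if (length(xs) == 0) {
      return(data.frame(x = integer(0), y = integer(0)))
    }
    ord <- sample.int(length(xs)) # draw order = thinning priority
    xs <- xs[ord]
    ys <- ys[ord]
    keep <- nms_keep(as.numeric(xs), as.numeric(ys), params$min_separation)
    data.frame(x = as.integer(xs[keep]), y = as.integer(ys[keep]))
  })
}

#' Render segmentation and detection probability maps
#'
#' Stands in for the output of learned segmentation/detection backends. The
#' segmentation map is the one-hot encoding of the merged
#' \{tumor, stroma, other\} truth, perturbed per channel with i.i.d.
#' Gaussian noise of sd `noise_sigma`, floored at 0 and renormalized so
#' channels sum to 1. The detection map places a Gaussian bump of radius
#' `blur_radius` (peak exactly 1) at every lymphocyte, adds a spatially
#' correlated Gaussian error field (sd `noise_sigma` before smoothing,
#' correlation length 3 x `blur_radius`) and clips to \[0, 1\].
#'
#' @param tissue A [tissue_map()].
#' @param points Data frame of lymphocyte points (`x`, `y`).
#' @param params A [synth_params()].
#' @return A list with `seg` (H x W x 3 array, channels tumor, stroma,
#'   other) and `det` (H x W matrix in \[0, 1\]).
#' @export
render_probability_maps <- function(tissue, points, params) {
  stopifnot(inherits(tissue, "tissue_map"), inherits(params, "synth_params"))
  if (!identical(dim(tissue$pixels), c(params$height, params$width))) {
    stop("`tissue` and `params` dimensions differ", call. = FALSE)
  }
  merged <- merge_classes(tissue)
  h <- nrow(merged)
  w <- ncol(merged)
  seg <- array(0, dim = c(h, w, 3L), dimnames = list(NULL, NULL, c("tumor", "stroma", "other")))
  seg[, , 1L] <- as.numeric(merged == 1L)
  seg[, , 2L] <- as.numeric(merged == 2L)
  seg[, , 3L] <- as.numeric(merged == 0L)

  det <- matrix(0, h, w)
  if (nrow(points) > 0) {
    if (params$blur_radius <= 0) {
      det[cbind(points$y + 1L, points$x + 1L)] <- 1
    } else {
      r <- ceiling(4 * params$blur_radius)
      for (i in seq_len(nrow(points))) {
        px <- points$x[i]
        py <- points$y[i]
        cx <- max(0L, px - r):min(w - 1L, px + r)
        cy <- max(0L, py - r):min(h - 1L, py + r)
        d2 <- outer((cy - py)^2, (cx - px)^2, `+`)
        bump <- exp(-d2 / (2 * params$blur_radius^2))
        det[cy + 1L, cx + 1L] <- pmax(det[cy + 1L, cx + 1L], bump)
      }
    }
  }

  if (params$noise_sigma > 0) {
    withr::with_seed(derive_seed(params$seed, 3L), {
      seg <- seg + array(rnorm(h * w * 3L, sd = params$noise_sigma), dim = dim(seg))
      noise <- matrix(rnorm(h * w, sd = params$noise_sigma), h, w)
      if (params$blur_radius > 0) {
        noise <- gaussian_smooth_fft(noise, 3 * params$blur_radius)
      }
      det <- pmin(pmax(det + noise, 0), 1)
    })
    seg[seg < 0] <- 0
    tot <- seg[, , 1L] + seg[, , 2L] + seg[, , 3L]
    flat <- tot <= 0 # all channels wiped out: fall back to uniform
    if (any(flat)) {
      for (k in 1:3) seg[, , k][flat] <- 1
      tot[flat] <- 3
    }
    for (k in 1:3) seg[, , k] <- seg[, , k] / tot
  }
  list(seg = seg, det = det)
}

#' Emit COCO annotations for lymphocyte points
#'
#' One record per point with a square bounding box of side `box_side`
#' centered on the point: top-left = round(center - box_side / 2) with
#' half-up rounding.
#'
#' @param points Data frame with `x`, `y`.
#' @param box_side Box side in pixels (default 12).
#' @param slide_id Image identifier recorded in the `images` block.
#' @param width,height Image size recorded in the `images` block.
#' @return A `coco_annotations` list with `images`, `annotations`,
#'   `categories`.
#' @export
#' @examples
#' emit_annotations(data.frame(x = 100, y = 50))$annotations[[1]]$bbox
emit_annotations <- function(points, box_side = 12, slide_id = "slide",
                             width = NA_integer_, height = NA_integer_) {
  if (box_side < 1) stop("`box_side` must be >= 1", call. = FALSE)
  anns <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    x0 <- round_half_up(points$x[i] - box_side / 2)
    y0 <- round_half_up(points$y[i] - box_side / 2)
    anns[[i]] <- list(
      id = i, image_id = 1L, category_id = 1L,
      bbox = c(x0, y0, box_side, box_side),
      area = box_side^2, iscrowd = 0L
    )
  }
  structure(
    list(
      images = list(list(
        id = 1L, file_name = paste0(slide_id, ".png"),
        width = width, height = height
      )),
      annotations = anns,
      categories = list(list(id = 1L, name = "lymphocyte"))
    ),
    class = "coco_annotations"
  )
}

#' Bounding-box centers of a COCO annotation set
#'
#' Inverse of the centering convention of [emit_annotations()]: the center
#' of bbox `[x0, y0, w, h]` is `(x0 + w/2, y0 + h/2)`.
#'
#' @param coco A `coco_annotations` object.
#' @return Data frame with columns `x`, `y`.
#' @export
coco_centers <- function(coco) {
  if (length(coco$annotations) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  bb <- t(vapply(coco$annotations, function(a) as.numeric(a$bbox), numeric(4)))
  data.frame(x = bb[, 1] + bb[, 3] / 2, y = bb[, 2] + bb[, 4] / 2)
}

#' Generate a synthetic cohort with reference TIL scores
#'
#' Writes, per slide, the fine tissue label raster (PNG + legend sidecar),
#' the corrupted segmentation and detection probability maps (32-bit TIFF),
#' and COCO annotations; plus a cohort-level reference-score CSV and a
#' manifest. Reference scores are computed from the noise-free ground truth
#' with the same scoring protocol the pipeline applies (256 px tiling,
#' background filtering, stroma-restricted counting, Eq.-style summation).
#' Slides receive a deterministic linear ramp of lymphocyte-rate multipliers
#' (`density_range`) so reference scores span a realistic range.
#'
#' @param n_slides Number of slides (>= 1).
#' @param params Base [synth_params()]; per-slide seeds derive from
#'   `params$seed`.
#' @param out_dir Output directory (created if needed).
#' @param density_range Length-2 numeric; lymphocyte-rate multipliers are
#'   evenly spaced over this range across slides.
#' @param tile_side,max_bg Tiling and background-filter settings used when
#'   computing reference scores.
#' @return Invisibly, a `cohort_manifest` list with `dir`, `manifest`
#'   (data frame), `scores` (data frame) and `params`.
#' @export
generate_cohort <- function(n_slides, params, out_dir,
                            density_range = c(0.3, 2.5),
                            tile_side = 256, max_bg = 0.65) {
  stopifnot(inherits(params, "synth_params"))
  if (n_slides < 1) stop("`n_slides` must be >= 1", call. = FALSE)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  slide_seeds <- withr::with_seed(
    derive_seed(params$seed, 4L),
    sample.int(2147483646L, n_slides)
  )
  mult <- if (n_slides == 1) 1 else seq(density_range[1], density_range[2], length.out = n_slides)
  write_legend_json(fine_class_legend(), file.path(out_dir, "legend.json"))

  rows <- vector("list", n_slides)
  scores <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    sid <- sprintf("slide_%03d", i)
    p_i <- params
    p_i$lympho_rate <- params$lympho_rate * mult[i]
    p_i$seed <- slide_seeds[i]
    class(p_i) <- "synth_params"
    tissue <- generate_tissue_map(p_i)
    points <- sample_lymphocyte_points(tissue, p_i)
    maps <- render_probability_maps(tissue, points, p_i)
    coco <- emit_annotations(points,
      slide_id = sid,
      width = p_i$width, height = p_i$height
    )

    truth <- slide_truth_score(tissue, points,
      tile_side = tile_side, max_bg = max_bg
    )

    tissue_file <- file.path(out_dir, paste0(sid, "_tissue.png"))
    seg_file <- file.path(out_dir, paste0(sid, "_seg.tif"))
    det_file <- file.path(out_dir, paste0(sid, "_det.tif"))
    coco_file <- file.path(out_dir, paste0(sid, "_coco.json"))
    write_label_raster(tissue$pixels, tissue_file)
    write_prob_raster(maps$seg, seg_file)
    write_prob_raster(maps$det, det_file)
    write_coco(coco, coco_file)

    rows[[i]] <- data.frame(
      slide_id = sid, width = p_i$width, height = p_i$height,
      n_points = nrow(points), seed = slide_seeds[i],
      density_multiplier = mult[i],
      tissue = basename(tissue_file), seg = basename(seg_file),
      det = basename(det_file), coco = basename(coco_file)
    )
    scores[[i]] <- data.frame(slide_id = sid, til_score = truth$score)
  }
  manifest <- do.call(rbind, rows)
  score_df <- do.call(rbind, scores)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write_scores(score_df, file.path(out_dir, "til-scores.csv"))
  meta <- list(
    n_slides = n_slides, seed = params$seed,
    density_range = density_range, tile_side = tile_side, max_bg = max_bg,
    noise_sigma = params$noise_sigma, blur_radius = params$blur_radius,
    fingerprint = config_fingerprint(params)
  )
  jsonlite::write_json(meta, file.path(out_dir, "cohort.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(structure(
    list(dir = out_dir, manifest = manifest, scores = score_df, params = params),
    class = "cohort_manifest"
  ))
}

# Reference TIL score from noise-free truth, using the pipeline's own
# scoring protocol (tiling + background filter on the fine labels, merged
# truth stroma, points as perfect detections).
slide_truth_score <- function(tissue, points, tile_side = 256, max_bg = 0.65,
                              lymphocyte_area = 256) {
  grid <- tile_image(tissue$pixels, tile_side)
  grid$windows$bg_fraction <- grid_background_fractions(
    tissue$pixels, grid,
    mode = "label", legend = tissue$legend
  )
  grid <- filter_patches(grid, max_bg)
  stroma <- merge_classes(tissue) == 2L
  dets <- points
  if (nrow(dets) > 0) dets$confidence <- 1 else dets$confidence <- numeric(0)
  score_slide(stroma, dets,
    grid = grid, slide_id = "truth",
    lymphocyte_area = lymphocyte_area
  )
}
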