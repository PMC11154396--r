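# ------------------------------------------------------------------------
# Stroma-restricted TIL scoring:
#   score = 100 * sum(TILs * 16 * 16) / sum(stroma area)
# with per-tile numerator/denominator sums aggregated before division,
# clipped to [0, 100]. The 16x16 = 256 px^2 lymphocyte footprint comes from
# an 8 um equivalent diameter at 0.5 um/px.
# ------------------------------------------------------------------------

#' Binary stroma mask from a segmentation map
#'
#' For a 3-channel probability map (tumor, stroma, other) a pixel is stroma
#' iff the per-pixel argmax channel is stroma, with ties resolved to the
#' lowest channel index (tumor before stroma before other). For a merged
#' label raster a pixel is stroma iff it carries the stroma code.
#'
#' @param seg H x W x 3 probability array or merged integer label matrix.
#' @return Logical H x W matrix.
#' @export
stroma_mask <- function(seg) {
  if (length(dim(seg)) == 3) {
    if (dim(seg)[3] != 3) {
      stop("segmentation map must have 3 channels (tumor, stroma, other)",
        call. = FALSE
      )
    }
    h <- dim(seg)[1]
    w <- dim(seg)[2]
    flat <- matrix(seg, h * w, 3L)
    winner <- max.col(flat, ties.method = "first")
    matrix(winner == 2L, h, w)
  } else if (is.matrix(seg)) {
    seg == merged_class_legend()[["stroma"]]
  } else {
    stop("`seg` must be a 3-channel array or a merged label matrix",
      call. = FALSE
    )
  }
}

#' Per-pixel argmax of a merged-class probability map
#'
#' @param seg H x W x 3 array with channels tumor, stroma, other.
#' @return Integer matrix over [merged_class_legend()] codes.
#' @export
seg_argmax <- function(seg) {
  if (length(dim(seg)) != 3 || dim(seg)[3] != 3) {
    stop("segmentation map must have 3 channels", call. = FALSE)
  }
  h <- dim(seg)[1]
  w <- dim(seg)[2]
  winner <- max.col(matrix(seg, h * w, 3L), ties.method = "first")
  codes <- c(1L, 2L, 0L) # channel order tumor, stroma, other
  matrix(codes[winner], h, w)
}

#' Count detections whose center lies on stroma
#'
#' Membership uses the rounded center pixel only; a lymphocyte is counted,
#' not its footprint.
#'
#' @param dets Detection data frame (`x`, `y`, 0-based).
#' @param stroma Logical/0-1 stroma raster.
#' @return Integer count.
#' @export
count_in_stroma <- function(dets, stroma) {
  if (nrow(dets) == 0) {
    return(0L)
  }
  px <- round_half_up(dets$x)
  py <- round_half_up(dets$y)
  h <- nrow(stroma)
  w <- ncol(stroma)
  if (any(px < 0 | px >= w | py < 0 | py >= h)) {
    stop("detection outside raster bounds", call. = FALSE)
  }
  sum(stroma[cbind(py + 1, px + 1)] > 0)
}

#' TIL score from counts
#'
#' `100 * n_tils * lymphocyte_area / stroma_pixels`, clipped to
#' \[0, 100\]. A zero stroma area makes the score undefined (`NA`, with a
#' warning): it asserts nothing about TIL density rather than asserting
#' zero.
#'
#' @param n_tils Number of lymphocytes counted within stroma.
#' @param stroma_pixels Stroma area in pixels.
#' @param lymphocyte_area Nominal lymphocyte footprint in px^2 (default
#'   16 x 16 = 256; see [lymphocyte_footprint_px2()]).
#' @return Clipped score in \[0, 100\], or `NA_real_` when undefined.
#' @export
#' @examples
#' compute_til_score(10, 25600) # 10.0
compute_til_score <- function(n_tils, stroma_pixels, lymphocyte_area = 256) {
  if (n_tils < 0 || stroma_pixels < 0 || lymphocyte_area <= 0) {
    stop("counts must be non-negative and `lymphocyte_area` positive",
      call. = FALSE
    )
  }
  if (stroma_pixels == 0) {
    warning("zero stroma area: TIL score undefined", call. = FALSE)
    return(NA_real_)
  }
  min(100, 100 * n_tils * lymphocyte_area / stroma_pixels)
}

#' Lymphocyte footprint in pixels squared
#'
#' Converts the nominal lymphocyte equivalent diameter (default 8 um) at a
#' given sampling resolution (default 0.5 um/px) into the square pixel
#' footprint used by the score numerator: `(diameter / resolution)^2`,
#' 16 x 16 = 256 px^2 at the defaults.
#'
#' @param diameter_um Lymphocyte equivalent diameter in micrometers.
#' @param resolution_um_per_px Sampling resolution in micrometers per pixel.
#' @return Footprint in px^2.
#' @export
lymphocyte_footprint_px2 <- function(diameter_um = 8, resolution_um_per_px = 0.5) {
  if (diameter_um <= 0 || resolution_um_per_px <= 0) {
    stop("diameter and resolution must be positive", call. = FALSE)
  }
  (diameter_um / resolution_um_per_px)^2
}

# Build the per-slide score record.
til_score_record <- function(slide_id, n_tils, stroma_pixels,
                             lymphocyte_area = 256) {
  defined <- stroma_pixels > 0
  raw <- if (defined) 100 * n_tils * lymphocyte_area / stroma_pixels else NA_real_
  score <- if (defined) min(100, raw) else NA_real_
  if (defined && raw > 100) {
    warning("TIL score for ", slide_id, " clipped from ",
      format(raw, digits = 4), " to 100",
      call. = FALSE
    )
  }
  if (!defined) {
    warning("slide ", slide_id, " has zero stroma area: score undefined",
      call. = FALSE
    )
  }
  structure(
    list(
      slide_id = slide_id,
      n_tils_in_stroma = as.integer(n_tils),
      stroma_pixels = as.numeric(stroma_pixels),
      lymphocyte_area = lymphocyte_area,
      raw_score = raw, score = score, defined = defined
    ),
    class = "til_score_record"
  )
}

#' @export
print.til_score_record <- function(x, ...) {
  cat(
    "<til_score_record>", x$slide_id, "- TILs in stroma:",
    x$n_tils_in_stroma, "| stroma px:", x$stroma_pixels, "| score:",
    if (x$defined) format(x$score, digits = 4) else "undefined", "\n"
  )
  invisible(x)
}

#' Aggregate per-tile counts into a slide TIL score
#'
#' Numerators and denominators are summed across a slide's retained tiles
#' before division, so the result equals [compute_til_score()] on the sums.
#'
#' @param patch_records Data frame with columns `n_tils` and
#'   `stroma_pixels`, one row per retained tile.
#' @param slide_id Slide identifier for the record.
#' @param lymphocyte_area Footprint in px^2 (default 256).
#' @return A `til_score_record`.
#' @export
slide_til_score <- function(patch_records, slide_id = "slide",
                            lymphocyte_area = 256) {
  if (nrow(patch_records) == 0) {
    return(til_score_record(slide_id, 0L, 0, lymphocyte_area))
  }
  til_score_record(
    slide_id,
    sum(patch_records$n_tils),
    sum(patch_records$stroma_pixels),
    lymphocyte_area
  )
}

#' Score one slide from its stroma mask and detections
#'
#' Computes per-tile (TIL count, stroma area) records over the retained
#' windows of `grid` — or over the whole slide when `grid` is `NULL` — and
#' aggregates them with [slide_til_score()]. Only the unpadded part of each
#' window contributes (padding carries neither stroma nor detections).
#'
#' @param stroma Logical/0-1 stroma raster.
#' @param dets Detection data frame (`x`, `y`; 0-based).
#' @param grid Optional `patch_grid` (already background-filtered).
#' @param slide_id Slide identifier.
#' @param lymphocyte_area Footprint in px^2.
#' @return A `til_score_record`.
#' @export
score_slide <- function(stroma, dets, grid = NULL, slide_id = "slide",
                        lymphocyte_area = 256) {
  h <- nrow(stroma)
  w <- ncol(stroma)
  if (is.null(grid)) {
    recs <- data.frame(
      n_tils = count_in_stroma(dets, stroma),
      stroma_pixels = sum(stroma > 0)
    )
    return(slide_til_score(recs, slide_id, lymphocyte_area))
  }
  px <- if (nrow(dets) > 0) round_half_up(dets$x) else integer(0)
  py <- if (nrow(dets) > 0) round_half_up(dets$y) else integer(0)
  if (length(px) > 0 && any(px < 0 | px >= w | py < 0 | py >= h)) {
    stop("detection outside raster bounds", call. = FALSE)
  }
  on_stroma <- if (length(px) > 0) stroma[cbind(py + 1, px + 1)] > 0 else logical(0)
  wins <- grid$windows
  n_tils <- integer(nrow(wins))
  area <- numeric(nrow(wins))
  for (i in seq_len(nrow(wins))) {
    x1 <- min(wins$x1[i], w)
    y1 <- min(wins$y1[i], h)
    area[i] <- sum(stroma[(wins$y0[i] + 1):y1, (wins$x0[i] + 1):x1] > 0)
    if (length(px) > 0) {
      inside <- px >= wins$x0[i] & px < x1 & py >= wins$y0[i] & py < y1
      n_tils[i] <- sum(inside & on_stroma)
    }
  }
  slide_til_score(
    data.frame(n_tils = n_tils, stroma_pixels = area),
    slide_id, lymphocyte_area
  )
}
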