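# ------------------------------------------------------------------------
# Tile preprocessing: 256x256 cropping with right/bottom zero padding,
# background filtering, 8 -> 3 class merging, and COCO-box rasterization.
# ------------------------------------------------------------------------

#' Tile a raster into fixed-size windows
#'
#' Covers the raster with `ceiling(H / tile_side) * ceiling(W / tile_side)`
#' half-open windows in row-major order. Edge windows extend past the raster
#' and record the right/bottom zero-padding needed to emit exact
#' `tile_side x tile_side` patches.
#'
#' @param raster 2-D matrix or 3-D array (or its `dim()` vector).
#' @param tile_side Tile side in pixels (default 256).
#' @return A `patch_grid` list with `tile_side`, `width`, `height` and a
#'   `windows` data frame (`x0`, `y0`, `x1`, `y1`, `pad_right`,
#'   `pad_bottom`).
#' @export
#' @examples
#' g <- tile_image(matrix(0, 300, 300))
#' g$windows
tile_image <- function(raster, tile_side = 256) {
  d <- if (is.numeric(raster) && is.null(dim(raster))) raster else dim(raster)
  if (is.null(d) || length(d) < 2) stop("`raster` must be 2-D or 3-D", call. = FALSE)
  h <- d[1]
  w <- d[2]
  if (h < 1 || w < 1) stop("empty raster", call. = FALSE)
  if (tile_side < 1) stop("`tile_side` must be >= 1", call. = FALSE)
  nty <- ceiling(h / tile_side)
  ntx <- ceiling(w / tile_side)
  ty <- rep(seq_len(nty) - 1L, each = ntx)
  tx <- rep(seq_len(ntx) - 1L, times = nty)
  x0 <- tx * tile_side
  y0 <- ty * tile_side
  windows <- data.frame(
    x0 = x0, y0 = y0,
    x1 = x0 + tile_side, y1 = y0 + tile_side,
    pad_right = pmax(0L, x0 + tile_side - w),
    pad_bottom = pmax(0L, y0 + tile_side - h)
  )
  structure(
    list(tile_side = tile_side, width = w, height = h, windows = windows),
    class = "patch_grid"
  )
}

#' Extract one zero-padded patch from a raster
#'
#' @param raster Matrix or 3-D array the grid was built for.
#' @param grid A `patch_grid` from [tile_image()].
#' @param i Window index (row of `grid$windows`).
#' @return A `tile_side x tile_side` patch (matrix or array), zero padded on
#'   the right/bottom where the window extends past the raster.
#' @export
extract_patch <- function(raster, grid, i) {
  wd <- grid$windows[i, ]
  t <- grid$tile_side
  rows <- (wd$y0 + 1):min(wd$y1, grid$height)
  cols <- (wd$x0 + 1):min(wd$x1, grid$width)
  if (length(dim(raster)) == 3) {
    out <- array(0, dim = c(t, t, dim(raster)[3]))
    out[seq_along(rows), seq_along(cols), ] <- raster[rows, cols, , drop = FALSE]
  } else {
    out <- matrix(0, t, t)
    out[seq_along(rows), seq_along(cols)] <- raster[rows, cols]
    storage.mode(out) <- storage.mode(raster)
  }
  out
}

#' Reassemble a raster from its patch grid
#'
#' Inverse of [tile_image()] + [extract_patch()]: crops each patch's padding
#' and places it at its window; the result is bit-identical to the tiled
#' raster.
#'
#' @param patches List of patches in `grid$windows` order.
#' @param grid The `patch_grid` they came from.
#' @return The reassembled matrix.
#' @export
reassemble_patches <- function(patches, grid) {
  out <- matrix(0, grid$height, grid$width)
  storage.mode(out) <- storage.mode(patches[[1]])
  for (i in seq_len(nrow(grid$windows))) {
    wd <- grid$windows[i, ]
    rows <- (wd$y0 + 1):min(wd$y1, grid$height)
    cols <- (wd$x0 + 1):min(wd$x1, grid$width)
    out[rows, cols] <- patches[[i]][seq_along(rows), seq_along(cols)]
  }
  out
}

#' Background fraction of a patch
#'
#' In `label` mode, the share of pixels whose fine class is `background`;
#' in `intensity` mode, the share of pixels whose grayscale luminance
#' exceeds `cutoff` (strictly), for unlabeled H&E-like tiles where bright
#' glass is background.
#'
#' @param patch Label matrix (`label` mode) or numeric image in \[0, 1\]
#'   (`intensity` mode; an H x W x 3 array is converted to luminance).
#' @param mode `"label"` or `"intensity"`.
#' @param legend Legend for label mode; must contain `background`.
#' @param cutoff Luminance cutoff for intensity mode (default 0.8).
#' @return Fraction in \[0, 1\].
#' @export
background_fraction <- function(patch, mode = c("label", "intensity"),
                                legend = fine_class_legend(), cutoff = 0.8) {
  mode <- match.arg(mode)
  if (mode == "label") {
    if (!"background" %in% names(legend)) {
      stop("legend has no 'background' class", call. = FALSE)
    }
    mean(patch == legend[["background"]])
  } else {
    if (length(dim(patch)) == 3) {
      patch <- 0.2126 * patch[, , 1] + 0.7152 * patch[, , 2] + 0.0722 * patch[, , 3]
    }
    mean(patch > cutoff)
  }
}

#' Background fractions for every window of a grid
#'
#' @param raster The raster the grid tiles (labels or intensities).
#' @inheritParams background_fraction
#' @param grid A `patch_grid`.
#' @return Numeric vector, one fraction per window. Zero-padded margins
#'   count as background in label mode (pad value 0 is the background code).
#' @export
grid_background_fractions <- function(raster, grid, mode = c("label", "intensity"),
                                      legend = fine_class_legend(), cutoff = 0.8) {
  mode <- match.arg(mode)
  vapply(
    seq_len(nrow(grid$windows)),
    function(i) {
      background_fraction(extract_patch(raster, grid, i),
        mode = mode,
        legend = legend, cutoff = cutoff
      )
    },
    numeric(1)
  )
}

#' Filter tiles by background fraction
#'
#' Retains windows whose background fraction does not exceed `max_bg`;
#' "exceeding" is strict, so a tile at exactly `max_bg` is retained.
#'
#' @param grid A `patch_grid` whose `windows` carry a `bg_fraction` column
#'   (see [grid_background_fractions()]).
#' @param max_bg Maximum tolerated background fraction (default 0.65).
#' @return The grid with `windows` restricted to the retained tiles.
#' @export
filter_patches <- function(grid, max_bg = 0.65) {
  if (is.null(grid$windows$bg_fraction)) {
    stop("grid windows have no `bg_fraction`; compute them first", call. = FALSE)
  }
  grid$windows <- grid$windows[grid$windows$bg_fraction <= max_bg, , drop = FALSE]
  rownames(grid$windows) <- NULL
  grid
}

#' Merge the eight fine tissue classes to tumor / stroma / other
#'
#' Invasive tumor maps to tumor; tumor-associated and inflamed stroma map to
#' stroma; every remaining class (in-situ tumor, healthy glands, necrosis,
#' rest, background) maps to other. The merged codes coincide with the fine
#' codes of their representatives, so the map is idempotent on already
#' merged rasters.
#'
#' @param x A [tissue_map()] or an integer label matrix.
#' @param legend Legend for matrix input.
#' @return Integer matrix over [merged_class_legend()] codes.
#' @export
merge_classes <- function(x, legend = fine_class_legend()) {
  if (inherits(x, "tissue_map")) {
    legend <- x$legend
    x <- x$pixels
  }
  bad <- setdiff(unique(as.vector(x)), unname(legend))
  if (length(bad) > 0) {
    stop("pixel value(s) absent from legend: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  lut <- fine_to_merged_lookup()
  out <- matrix(lut[x + 1L], nrow(x), ncol(x))
  storage.mode(out) <- "integer"
  out
}

#' Rasterize COCO boxes to a binary lymphocyte mask
#'
#' Each annotation is painted as a `box_side` square centered on its box
#' center (top-left = round(center - box_side / 2), half-up), clipped to the
#' raster; overlapping boxes union.
#'
#' @param coco A `coco_annotations` object.
#' @param shape `c(H, W)` of the output mask.
#' @param box_side Painted square side (default 12).
#' @return Integer H x W matrix with lymphocyte = 1, background = 0.
#' @export
boxes_to_mask <- function(coco, shape, box_side = 12) {
  if (length(shape) != 2 || any(shape < 1)) {
    stop("`shape` must be positive c(H, W)", call. = FALSE)
  }
  h <- shape[1]
  w <- shape[2]
  mask <- matrix(0L, h, w)
  for (a in coco$annotations) {
    bb <- as.numeric(a$bbox)
    if (length(bb) != 4 || bb[3] < 0 || bb[4] < 0) {
      stop("malformed bbox in annotation id ", a$id, call. = FALSE)
    }
    cx <- bb[1] + bb[3] / 2
    cy <- bb[2] + bb[4] / 2
    x0 <- round_half_up(cx - box_side / 2)
    y0 <- round_half_up(cy - box_side / 2)
    xs <- max(0, x0):min(w - 1, x0 + box_side - 1)
    ys <- max(0, y0):min(h - 1, y0 + box_side - 1)
    if (length(xs) > 0 && length(ys) > 0 && xs[1] <= xs[length(xs)] &&
      ys[1] <= ys[length(ys)]) {
      mask[ys + 1, xs + 1] <- 1L
    }
  }
  mask
}

#' Drop patches without any lymphocyte
#'
#' Detection-dataset assembly step: retains only patches whose paired mask
#' has at least one foreground pixel. Applied when assembling training
#' data, never during evaluation or scoring.
#'
#' @param patches List of patches.
#' @param masks List of binary masks, same length.
#' @return List with filtered `patches`, `masks` and the logical `kept`
#'   vector.
#' @export
drop_lymphocyte_free_patches <- function(patches, masks) {
  if (length(patches) != length(masks)) {
    stop("`patches` and `masks` must have equal length", call. = FALSE)
  }
  kept <- vapply(masks, function(m) any(m > 0), logical(1))
  list(patches = patches[kept], masks = masks[kept], kept = kept)
}
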