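# ------------------------------------------------------------------------
# Readers/writers: 8-bit PNG label rasters with a JSON legend sidecar,
# 32-bit TIFF probability maps, COCO JSON annotations, detection and score
# CSVs, YAML configs.
# ------------------------------------------------------------------------

#' Write / read an integer label raster (8-bit PNG)
#'
#' Codes 0-255 are stored losslessly; the legend travels in a JSON sidecar
#' (see [write_legend_json()]).
#'
#' @param m Integer matrix of class codes.
#' @param path Output path.
#' @return `write_label_raster()`: the path, invisibly.
#' @export
write_label_raster <- function(m, path) {
  if (any(m < 0 | m > 255)) stop("label codes must be 0-255", call. = FALSE)
  png::writePNG(m / 255, path)
  invisible(path)
}

#' @rdname write_label_raster
#' @return `read_label_raster()`: the integer matrix.
#' @export
read_label_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) {
    stop("expected a single-band label raster, got ", dim(img)[3],
      " bands: ", path,
      call. = FALSE
    )
  }
  out <- round_half_up(img * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write / read a probability raster (32-bit TIFF)
#'
#' Single-band matrices (detection maps) or H x W x 3 arrays (merged-class
#' segmentation maps); values must be in \[0, 1\] and round-trip within
#' 32-bit precision.
#'
#' @param x Numeric matrix or array with values in \[0, 1\].
#' @param path Output path.
#' @return `write_prob_raster()`: the path, invisibly.
#' @export
write_prob_raster <- function(x, path) {
  if (min(x) < 0 || max(x) > 1) {
    stop("probability raster values must lie in [0, 1]", call. = FALSE)
  }
  tiff::writeTIFF(x, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_prob_raster
#' @param bands Expected band count (`NULL` to accept any).
#' @return `read_prob_raster()`: matrix (1 band) or array.
#' @export
read_prob_raster <- function(path, bands = NULL) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  got <- if (length(dim(img)) == 3) dim(img)[3] else 1L
  if (!is.null(bands) && got != bands) {
    stop("expected ", bands, " band(s), got ", got, ": ", path, call. = FALSE)
  }
  img
}

#' Write / read a class legend sidecar (JSON)
#'
#' @param legend Named integer vector (name -> code).
#' @param path Output path.
#' @return `write_legend_json()`: the path, invisibly.
#' @export
write_legend_json <- function(legend, path) {
  obj <- as.list(names(legend))
  names(obj) <- as.character(unname(legend))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_legend_json
#' @return `read_legend_json()`: the named integer vector.
#' @export
read_legend_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  codes <- as.integer(names(obj))
  out <- codes
  names(out) <- unlist(obj, use.names = FALSE)
  out
}

#' Write / read COCO lymphocyte annotations
#'
#' JSON with `images`, `annotations` (each with a `[x, y, w, h]` bbox) and
#' `categories`; bbox values round-trip exactly. Only the `lymphocyte`
#' category is accepted.
#'
#' @param coco A `coco_annotations` object.
#' @param path File path.
#' @return `write_coco()`: the path, invisibly.
#' @export
write_coco <- function(coco, path) {
  jsonlite::write_json(unclass(coco), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco
#' @return `read_coco()`: the `coco_annotations` object.
#' @export
read_coco <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(obj[[key]])) {
      stop("COCO file missing '", key, "': ", path, call. = FALSE)
    }
  }
  known <- vapply(obj$categories, function(ct) ct$name, character(1))
  if (!all(known %in% "lymphocyte")) {
    stop("unknown categor(ies): ",
      paste(setdiff(known, "lymphocyte"), collapse = ", "),
      call. = FALSE
    )
  }
  for (a in obj$annotations) {
    if (is.null(a$bbox) || length(a$bbox) != 4) {
      stop("annotation id ", if (is.null(a$id)) "?" else a$id,
        " has no valid bbox",
        call. = FALSE
      )
    }
  }
  obj$annotations <- lapply(obj$annotations, function(a) {
    a$bbox <- as.numeric(unlist(a$bbox))
    a
  })
  structure(obj, class = "coco_annotations")
}

#' Write / read detections as CSV
#'
#' Columns: `slide_id`, `x`, `y`, `confidence`.
#'
#' @param dets Detection data frame.
#' @param path File path.
#' @param slide_id Slide identifier column value.
#' @return `write_detections()`: the path, invisibly.
#' @export
write_detections <- function(dets, path, slide_id = "slide") {
  df <- data.frame(
    slide_id = rep(slide_id, nrow(dets)),
    x = dets$x, y = dets$y, confidence = dets$confidence
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @return `read_detections()`: the data frame.
#' @export
read_detections <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read per-slide TIL scores as CSV
#'
#' Schema: `slide_id`, `til_score` plus optional provenance columns;
#' undefined scores are stored as `NA`. Numeric columns are written with
#' full (17 significant digit) precision so scores round-trip exactly.
#'
#' @param df Data frame with at least `slide_id` and `til_score`.
#' @param path File path.
#' @return `write_scores()`: the path, invisibly.
#' @export
write_scores <- function(df, path) {
  stopifnot(all(c("slide_id", "til_score") %in% names(df)))
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @return `read_scores()`: the data frame.
#' @export
read_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("slide_id", "til_score") %in% names(df))) {
    stop("score CSV must have columns slide_id, til_score: ", path,
      call. = FALSE
    )
  }
  df
}

# Order-stable fingerprint of a config/params object, recorded in run
# metadata so outputs can be traced to the settings that produced them.
config_fingerprint <- function(x) {
  s <- paste(deparse(x[order(names(unclass(x)))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
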