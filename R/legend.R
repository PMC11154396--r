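#' Fine tissue-class legend
#'
#' The eight fine tissue classes used for ground-truth label rasters, as a
#' named integer vector mapping class name to pixel code. `background` is
#' code 0 so that zero-padded tile margins count as background.
#'
#' @return Named integer vector of length 8.
#' @export
#' @examples
#' fine_class_legend()
fine_class_legend <- function() {
  c(
    background = 0L,
    invasive_tumor = 1L,
    tumor_assoc_stroma = 2L,
    in_situ_tumor = 3L,
    healthy_glands = 4L,
    necrosis = 5L,
    inflamed_stroma = 6L,
    rest = 7L
  )
}

#' Merged three-class legend
#'
#' The coarse classes used for TIL scoring: tumor, stroma, other. Codes are
#' chosen so that applying the fine-to-merged map to an already-merged raster
#' is the identity (other = background code 0, tumor = invasive-tumor code 1,
#' stroma = tumor-associated-stroma code 2).
#'
#' @return Named integer vector of length 3.
#' @export
merged_class_legend <- function() {
  c(other = 0L, tumor = 1L, stroma = 2L)
}

# fine code -> merged code lookup (index = fine code + 1)
fine_to_merged_lookup <- function() {
  lut <- rep(0L, 8L) # default: other
  lut[fine_class_legend()[["invasive_tumor"]] + 1L] <- 1L
  lut[fine_class_legend()[["tumor_assoc_stroma"]] + 1L] <- 2L
  lut[fine_class_legend()[["inflamed_stroma"]] + 1L] <- 2L
  lut
}

#' Construct a tissue label map
#'
#' Bundles an integer label raster with its legend and checks that every
#' pixel value is covered by the legend.
#'
#' @param pixels Integer matrix of class codes (rows = y, columns = x).
#' @param legend Named integer vector mapping class name to code.
#' @return An object of class `tissue_map` with elements `pixels` and
#'   `legend`.
#' @export
tissue_map <- function(pixels, legend = fine_class_legend()) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  bad <- setdiff(unique(as.vector(pixels)), unname(legend))
  if (length(bad) > 0) {
    stop("pixel value(s) absent from legend: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(list(pixels = pixels, legend = legend), class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(
    "<tissue_map>", nrow(x$pixels), "x", ncol(x$pixels), "px,",
    length(x$legend), "classes\n"
  )
  print(table(factor(as.vector(x$pixels),
    levels = unname(x$legend),
    labels = names(x$legend)
  )))
  invisible(x)
}

#' @export
dim.tissue_map <- function(x) dim(x$pixels)
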