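# ------------------------------------------------------------------------
# Detection post-processing: probability threshold (strict > 0.1) then
# greedy distance-based NMS at 12 px, yielding a confidence-ranked point
# set with a guaranteed minimum pairwise separation.
# ------------------------------------------------------------------------

#' Extract supra-threshold candidates from a detection probability map
#'
#' One candidate per pixel whose value strictly exceeds `tau`, with
#' confidence equal to the pixel value. Candidates are sorted by confidence
#' descending; ties are broken by `(y, x)` lexicographic order so the
#' downstream greedy suppression is deterministic.
#'
#' @param det_map Numeric matrix with values in \[0, 1\].
#' @param tau Retention threshold (default 0.1; strict "exceeding").
#' @return Data frame with columns `x`, `y` (0-based), `confidence`.
#' @export
#' @examples
#' m <- matrix(0, 8, 8); m[3, 5] <- 0.7
#' extract_candidates(m)
extract_candidates <- function(det_map, tau = 0.1) {
  if (!is.matrix(det_map)) stop("`det_map` must be a matrix", call. = FALSE)
  rng <- range(det_map)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("`det_map` values must lie in [0, 1]", call. = FALSE)
  }
  idx <- which(det_map > tau)
  if (length(idx) == 0) {
    return(data.frame(x = integer(0), y = integer(0), confidence = numeric(0)))
  }
  h <- nrow(det_map)
  cand <- data.frame(
    x = (idx - 1L) %/% h,
    y = (idx - 1L) %% h,
    confidence = det_map[idx]
  )
  cand <- cand[order(-cand$confidence, cand$y, cand$x), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Greedy distance-based non-maximum suppression
#'
#' Scans candidates in confidence order and keeps a candidate if and only
#' if its Euclidean distance to every already-kept detection is at least
#' `nms_distance`; a candidate strictly closer than `nms_distance` to a
#' kept one is suppressed. Two detections exactly `nms_distance` apart are
#' both kept (two 12 px boxes whose centers are 12 apart do not overlap).
#'
#' @param candidates Data frame from [extract_candidates()] (confidence
#'   descending, ties by `(y, x)`).
#' @param nms_distance Suppression distance in pixels (default 12).
#' @return A `detection_set`: the kept rows, with attribute
#'   `nms_distance`.
#' @export
distance_nms <- function(candidates, nms_distance = 12) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0) {
    out <- candidates
  } else {
    keep <- nms_keep(
      as.numeric(candidates$x), as.numeric(candidates$y),
      nms_distance
    )
    out <- candidates[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out,
    nms_distance = nms_distance,
    class = c("detection_set", "data.frame")
  )
}

#' Detect lymphocytes in a probability map
#'
#' Composition of [extract_candidates()] and [distance_nms()]: threshold at
#' `tau`, then select peaks at least `nms_distance` apart.
#'
#' @inheritParams extract_candidates
#' @inheritParams distance_nms
#' @return A `detection_set` data frame (`x`, `y`, `confidence`).
#' @export
detect_lymphocytes <- function(det_map, tau = 0.1, nms_distance = 12) {
  distance_nms(extract_candidates(det_map, tau), nms_distance)
}
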