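# ------------------------------------------------------------------------
# Evaluation stack: per-class Dice, greedy radius matching (TP within 8 px,
# inclusive), FROC curves with the score averaged at six fixed FP/image
# operating points, and Pearson correlation of TIL scores.
# ------------------------------------------------------------------------

#' Dice overlap of two binary masks
#'
#' `2 |P intersect G| / (|P| + |G|)`; ranges from 0 (no overlap) to 1
#' (perfect overlap). Two empty masks agree perfectly on absence and score
#' 1.
#'
#' @param pred,gt Binary (logical or 0/1) matrices of equal shape.
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) {
    stop("`pred` and `gt` shapes differ", call. = FALSE)
  }
  p <- pred > 0
  g <- gt > 0
  denom <- sum(p) + sum(g)
  if (denom == 0) {
    return(1)
  }
  2 * sum(p & g) / denom
}

#' Per-class Dice over merged tissue rasters
#'
#' Dice of each class's binary indicator over \{tumor, stroma, other\},
#' plus the reported `average` — the mean of the tumor and stroma scores
#' only, matching the convention of headline segmentation tables.
#'
#' @param pred,gt Integer rasters over [merged_class_legend()] codes.
#' @return Named numeric: `tumor`, `stroma`, `other`, `average`.
#' @export
per_class_dice <- function(pred, gt) {
  lg <- merged_class_legend()
  out <- c(
    tumor = dice(pred == lg[["tumor"]], gt == lg[["tumor"]]),
    stroma = dice(pred == lg[["stroma"]], gt == lg[["stroma"]]),
    other = dice(pred == lg[["other"]], gt == lg[["other"]])
  )
  c(out, average = unname((out[["tumor"]] + out[["stroma"]]) / 2))
}

#' Greedy one-to-one matching of detections to ground-truth points
#'
#' Predictions are visited in confidence-descending order; each claims the
#' nearest still-unmatched ground-truth point within `match_radius`
#' (inclusive: distance exactly `match_radius` is a true positive).
#' Unmatched predictions are false positives; unmatched ground truth,
#' false negatives.
#'
#' @param dets Detection data frame (`x`, `y`, optional `confidence`).
#' @param gt Data frame of ground-truth points (`x`, `y`).
#' @param match_radius Matching radius in pixels (default 8).
#' @return A `match_result` list: `tp`, `fp`, `fn`, and `pairs`
#'   (`pred`, `gt`, `distance`).
#' @export
match_detections <- function(dets, gt, match_radius = 8) {
  np <- nrow(dets)
  ng <- nrow(gt)
  if (np > 0 && !is.null(dets$confidence)) {
    ord <- order(-dets$confidence, dets$y, dets$x)
  } else {
    ord <- seq_len(np)
  }
  matched <- rep(FALSE, ng)
  pair_pred <- integer(0)
  pair_gt <- integer(0)
  pair_d <- numeric(0)
  for (i in ord) {
    if (ng == 0 || all(matched)) break
    d <- sqrt((gt$x - dets$x[i])^2 + (gt$y - dets$y[i])^2)
    d[matched] <- Inf
    j <- which.min(d)
    if (d[j] <= match_radius) {
      matched[j] <- TRUE
      pair_pred <- c(pair_pred, i)
      pair_gt <- c(pair_gt, j)
      pair_d <- c(pair_d, d[j])
    }
  }
  tp <- length(pair_pred)
  structure(
    list(
      tp = tp, fp = np - tp, fn = ng - tp,
      pairs = data.frame(pred = pair_pred, gt = pair_gt, distance = pair_d)
    ),
    class = "match_result"
  )
}

#' FROC curve over a set of images
#'
#' Free-response operating characteristic: at each threshold (the unique
#' detection confidences, descending) detections with confidence at or
#' above the threshold are matched per image and the operating point
#' (average false positives per image, sensitivity) is recorded. Because
#' matching is greedy in confidence order, the match at any threshold is a
#' prefix of the full-set match, so each image is matched once.
#'
#' @param per_image List of `list(detections = , gt = )` pairs, one per
#'   image.
#' @param match_radius Matching radius in pixels (default 8).
#' @return A `froc_curve` data frame: `threshold`, `avg_fp_per_image`,
#'   `sensitivity` (thresholds descending). Zero rows when there are no
#'   detections.
#' @export
froc_curve <- function(per_image, match_radius = 8) {
  if (length(per_image) == 0) stop("need at least one image", call. = FALSE)
  total_gt <- sum(vapply(per_image, function(im) nrow(im$gt), numeric(1)))
  if (total_gt == 0) {
    stop("no ground-truth points: sensitivity undefined", call. = FALSE)
  }
  n_img <- length(per_image)
  conf <- numeric(0)
  is_tp <- logical(0)
  for (im in per_image) {
    dets <- im$detections
    if (nrow(dets) == 0) next
    m <- match_detections(dets, im$gt, match_radius)
    tp_flag <- rep(FALSE, nrow(dets))
    tp_flag[m$pairs$pred] <- TRUE
    conf <- c(conf, dets$confidence)
    is_tp <- c(is_tp, tp_flag)
  }
  if (length(conf) == 0) {
    return(structure(
      data.frame(
        threshold = numeric(0), avg_fp_per_image = numeric(0),
        sensitivity = numeric(0)
      ),
      class = c("froc_curve", "data.frame")
    ))
  }
  ord <- order(-conf)
  conf <- conf[ord]
  is_tp <- is_tp[ord]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  thresholds <- unique(conf)
  # last index with confidence >= each threshold
  last_at <- vapply(thresholds, function(t) max(which(conf >= t)), numeric(1))
  structure(
    data.frame(
      threshold = thresholds,
      avg_fp_per_image = cum_fp[last_at] / n_img,
      sensitivity = cum_tp[last_at] / total_gt
    ),
    class = c("froc_curve", "data.frame")
  )
}

#' FROC score at fixed false-positive operating points
#'
#' For each target rate, the sensitivity is the best sensitivity among
#' operating points whose average FP/image does not exceed the target
#' (step rule, no extrapolation; 0 when no point qualifies). The score is
#' the mean over the targets.
#'
#' @param curve A `froc_curve`.
#' @param fp_targets FP/image operating points (default
#'   `c(10, 20, 50, 100, 200, 300)`).
#' @return Mean sensitivity over the targets, in \[0, 1\].
#' @export
froc_score <- function(curve, fp_targets = c(10, 20, 50, 100, 200, 300)) {
  sens <- vapply(fp_targets, function(t) {
    ok <- curve$avg_fp_per_image <= t
    if (any(ok)) max(curve$sensitivity[ok]) else 0
  }, numeric(1))
  mean(sens)
}

#' Pearson correlation between predicted and reference TIL scores
#'
#' Slides with an undefined score on either side are excluded pairwise.
#' Fewer than 3 complete pairs, or zero variance in either vector, leave
#' the correlation undefined and raise an error.
#'
#' @param pred,ref Numeric vectors of equal length (may contain `NA`).
#' @return Product-moment correlation in \[-1, 1\].
#' @export
pearson_scores <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` lengths differ", call. = FALSE)
  }
  ok <- !is.na(pred) & !is.na(ref)
  if (sum(ok) < 3) {
    stop("fewer than 3 complete score pairs: correlation undefined",
      call. = FALSE
    )
  }
  p <- pred[ok]
  r <- ref[ok]
  if (sd(p) == 0 || sd(r) == 0) {
    stop("zero variance in scores: correlation undefined", call. = FALSE)
  }
  cor(p, r)
}

#' @importFrom stats sd
NULL
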