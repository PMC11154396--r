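# Independent reference implementations used as oracles. Written as plain
# double loops so they share no code path with the package.

# Brute-force greedy hard-core selection over candidates already sorted by
# priority: keep a candidate iff its distance to every kept one is >= d.
ref_nms <- function(cand, d) {
  keep <- logical(nrow(cand))
  kx <- numeric(0)
  ky <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (length(kx) > 0) {
      for (j in seq_along(kx)) {
        if ((cand$x[i] - kx[j])^2 + (cand$y[i] - ky[j])^2 < d^2) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      keep[i] <- TRUE
      kx <- c(kx, cand$x[i])
      ky <- c(ky, cand$y[i])
    }
  }
  cand[keep, , drop = FALSE]
}

# Greedy confidence-ordered one-to-one matcher: each prediction (confidence
# descending) claims its nearest unmatched ground-truth point within r.
ref_match <- function(dets, gt, r) {
  ord <- if (nrow(dets) > 0 && !is.null(dets$confidence)) {
    order(-dets$confidence, dets$y, dets$x)
  } else {
    seq_len(nrow(dets))
  }
  taken <- rep(FALSE, nrow(gt))
  tp <- 0L
  tp_rows <- integer(0)
  for (i in ord) {
    best <- NA_integer_
    best_d <- Inf
    for (j in seq_len(nrow(gt))) {
      if (taken[j]) next
      dd <- sqrt((dets$x[i] - gt$x[j])^2 + (dets$y[i] - gt$y[j])^2)
      if (dd < best_d) {
        best_d <- dd
        best <- j
      }
    }
    if (!is.na(best) && best_d <= r) {
      taken[best] <- TRUE
      tp <- tp + 1L
      tp_rows <- c(tp_rows, i)
    }
  }
  list(tp = tp, fp = nrow(dets) - tp, fn = nrow(gt) - tp, tp_rows = tp_rows)
}

# Per-threshold brute-force FROC: rematch every image from scratch at every
# unique confidence.
ref_froc <- function(per_image, r) {
  conf <- unlist(lapply(per_image, function(im) im$detections$confidence))
  total_gt <- sum(vapply(per_image, function(im) nrow(im$gt), numeric(1)))
  thresholds <- sort(unique(conf), decreasing = TRUE)
  out <- data.frame(
    threshold = thresholds,
    avg_fp_per_image = NA_real_, sensitivity = NA_real_
  )
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    tp <- 0L
    fp <- 0L
    for (im in per_image) {
      sub <- im$detections[im$detections$confidence >= t, , drop = FALSE]
      m <- ref_match(sub, im$gt, r)
      tp <- tp + m$tp
      fp <- fp + m$fp
    }
    out$avg_fp_per_image[k] <- fp / length(per_image)
    out$sensitivity[k] <- tp / total_gt
  }
  out
}

ref_froc_score <- function(curve, targets) {
  vals <- numeric(length(targets))
  for (k in seq_along(targets)) {
    best <- 0
    for (i in seq_len(nrow(curve))) {
      if (curve$avg_fp_per_image[i] <= targets[k] &&
        curve$sensitivity[i] > best) {
        best <- curve$sensitivity[i]
      }
    }
    vals[k] <- best
  }
  mean(vals)
}

# 8-connected component labeling by flood fill (queue based).
label_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  next_id <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] != 0L) next
    next_id <- next_id + 1L
    queue <- start
    lab[start] <- next_id
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- (cur - 1L) %% h + 1L
      c0 <- (cur - 1L) %/% h + 1L
      for (dr in -1:1) {
        for (dc in -1:1) {
          rr <- r0 + dr
          cc <- c0 + dc
          if (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
            mask[rr, cc] > 0 && lab[rr, cc] == 0L) {
            lab[rr, cc] <- next_id
            queue <- c(queue, (cc - 1L) * h + rr)
          }
        }
      }
    }
  }
  lab
}

# Centroids (0-based x, y) of labeled components.
component_centroids <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  h <- nrow(lab)
  data.frame(
    x = vapply(ids, function(i) mean(((which(lab == i)) - 1L) %/% h), numeric(1)),
    y = vapply(ids, function(i) mean(((which(lab == i)) - 1L) %% h), numeric(1))
  )
}

# Random candidate sets for NMS stress tests.
random_candidates <- function(n, extent = 200) {
  cand <- data.frame(
    x = round(runif(n, 0, extent)),
    y = round(runif(n, 0, extent)),
    confidence = runif(n)
  )
  cand <- cand[order(-cand$confidence, cand$y, cand$x), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# Compact generator settings for fast unit tests.
small_params <- function(...) {
  synth_params(
    width = 128, height = 128,
    class_fractions = c(
      invasive_tumor = 0.3, tumor_assoc_stroma = 0.25,
      inflamed_stroma = 0.2, background = 0.25
    ),
    lympho_rate = c(
      invasive_tumor = 2e-4, tumor_assoc_stroma = 1e-3,
      inflamed_stroma = 3e-3, background = 0
    ),
    blob_scale = 12,
    ...
  )
}
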