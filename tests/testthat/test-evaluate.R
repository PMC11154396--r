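test_that("dice follows set-cardinality arithmetic", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dice(a, a), 1.0)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice(a, b), 0.0)

  # |P| = |G| = 100, |P n G| = 50 -> 0.5
  p <- matrix(0, 20, 20)
  g <- matrix(0, 20, 20)
  p[1:100] <- 1
  g[51:150] <- 1
  expect_equal(dice(p, g), 0.5)

  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1.0) # both empty
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes differ")
})

test_that("per-class dice equals independent binary dice; average covers tumor and stroma", {
  set.seed(11)
  for (k in 1:20) {
    pr <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    gt <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
    d <- per_class_dice(pr, gt)
    for (cl in c(tumor = 1, stroma = 2, other = 0)) {
      nm <- names(which(c(tumor = 1, stroma = 2, other = 0) == cl))
      inter <- sum(pr == cl & gt == cl)
      expect_equal(d[[nm]], 2 * inter / (sum(pr == cl) + sum(gt == cl)))
    }
    expect_equal(d[["average"]], (d[["tumor"]] + d[["stroma"]]) / 2)
  }

  same <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
  expect_true(all(per_class_dice(same, same) == 1))
})

test_that("matching is inclusive at the radius and greedy in confidence", {
  gt <- data.frame(x = 0, y = 0)
  near <- data.frame(x = 7, y = 0, confidence = 0.9)
  m <- match_detections(near, gt, 8)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))

  far <- data.frame(x = 9, y = 0, confidence = 0.9)
  m2 <- match_detections(far, gt, 8)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))

  # two predictions near one truth: the higher confidence claims it
  two <- data.frame(x = c(5, 3), y = 0, confidence = c(0.8, 0.9))
  m3 <- match_detections(two, gt, 8)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(1, 1, 0))
  expect_equal(m3$pairs$pred, 2) # the 0.9 prediction (row 2)
  expect_equal(m3$pairs$distance, 3)
})

test_that("matching equals the reference greedy matcher on random inputs", {
  set.seed(23)
  for (k in 1:40) {
    np <- sample(0:8, 1)
    ng <- sample(0:8, 1)
    dets <- data.frame(
      x = runif(np, 0, 30), y = runif(np, 0, 30),
      confidence = runif(np)
    )
    gt <- data.frame(x = runif(ng, 0, 30), y = runif(ng, 0, 30))
    got <- match_detections(dets, gt, 8)
    want <- ref_match(dets, gt, 8)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_setequal(got$pairs$pred, want$tp_rows)
    expect_true(all(got$pairs$distance <= 8))
    expect_equal(got$tp + got$fn, ng)
    expect_equal(got$tp + got$fp, np)
  }
})

test_that("the FROC curve reproduces the worked two-image example", {
  # image 1: gt at (0,0), (50,50); detections conf 1.0 TP and 0.9 FP
  # image 2: gt at (0,0), (50,50); detections conf 0.8 TP and 0.7 FP
  per_image <- list(
    list(
      detections = data.frame(
        x = c(0, 25), y = c(0, 25),
        confidence = c(1.0, 0.9)
      ),
      gt = data.frame(x = c(0, 50), y = c(0, 50))
    ),
    list(
      detections = data.frame(
        x = c(50, 25), y = c(50, 25),
        confidence = c(0.8, 0.7)
      ),
      gt = data.frame(x = c(0, 50), y = c(0, 50))
    )
  )
  curve <- froc_curve(per_image, 8)
  expect_equal(curve$threshold, c(1.0, 0.9, 0.8, 0.7))
  expect_equal(curve$avg_fp_per_image, c(0, 0.5, 0.5, 1.0))
  expect_equal(curve$sensitivity, c(0.25, 0.25, 0.5, 0.5))
})

test_that("FROC degenerate cases: perfect detector, empty detector, no truth", {
  perfect <- list(list(
    detections = data.frame(x = c(0, 50), y = c(0, 50), confidence = c(1, 1)),
    gt = data.frame(x = c(0, 50), y = c(0, 50))
  ))
  curve <- froc_curve(perfect, 8)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$avg_fp_per_image, 0)
  expect_equal(curve$sensitivity, 1)
  expect_equal(froc_score(curve), 1.0)

  none <- list(list(
    detections = data.frame(x = numeric(0), y = numeric(0), confidence = numeric(0)),
    gt = data.frame(x = 0, y = 0)
  ))
  empty_curve <- froc_curve(none, 8)
  expect_equal(nrow(empty_curve), 0)
  expect_equal(froc_score(empty_curve), 0.0)

  no_truth <- list(list(
    detections = data.frame(x = 0, y = 0, confidence = 1),
    gt = data.frame(x = numeric(0), y = numeric(0))
  ))
  expect_error(froc_curve(no_truth, 8), "sensitivity undefined")
})

test_that("the FROC score applies the step rule at each FP target", {
  curve <- structure(
    data.frame(
      threshold = c(0.9, 0.6, 0.3),
      avg_fp_per_image = c(5, 15, 40),
      sensitivity = c(0.6, 0.75, 0.9)
    ),
    class = c("froc_curve", "data.frame")
  )
  # targets 10 -> 0.6; 20 -> 0.75; 50,100,200,300 -> 0.9
  expect_equal(froc_score(curve), (0.6 + 0.75 + 4 * 0.9) / 6)
  expect_equal(froc_score(curve), ref_froc_score(curve, c(10, 20, 50, 100, 200, 300)))
})

test_that("FROC curve and score equal brute-force recomputation on random data", {
  set.seed(47)
  for (k in 1:10) {
    n_img <- sample(2:5, 1)
    per_image <- lapply(seq_len(n_img), function(i) {
      ng <- sample(1:15, 1)
      np <- sample(0:20, 1)
      list(
        detections = data.frame(
          x = runif(np, 0, 100), y = runif(np, 0, 100),
          confidence = runif(np)
        ),
        gt = data.frame(x = runif(ng, 0, 100), y = runif(ng, 0, 100))
      )
    })
    got <- froc_curve(per_image, 8)
    want <- ref_froc(per_image, 8)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$avg_fp_per_image, want$avg_fp_per_image)
    expect_equal(got$sensitivity, want$sensitivity)
    # monotone as the threshold falls
    expect_true(all(diff(got$avg_fp_per_image) >= 0))
    expect_true(all(diff(got$sensitivity) >= 0))
    expect_true(all(got$sensitivity >= 0 & got$sensitivity <= 1))
  }
})

test_that("Pearson handles linear pairs, sign flips and undefined cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_scores(x, x), 1.0)
  expect_equal(pearson_scores(x, 2 * x), 1.0)
  expect_equal(pearson_scores(x, -x), -1.0)

  with_na <- c(1, 2, NA, 4, 5)
  expect_equal(pearson_scores(with_na, x), 1.0) # pairwise exclusion

  expect_error(pearson_scores(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_scores(c(1, NA, NA, 4), c(1, 2, 3, 4)), "fewer than 3")
  expect_error(pearson_scores(1:3, 1:4), "lengths differ")
})
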