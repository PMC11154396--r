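test_that("degenerate single-class fractions give a constant raster", {
  p <- synth_params(
    width = 64, height = 64,
    class_fractions = c(background = 1.0),
    lympho_rate = c(background = 0), seed = 3
  )
  tm <- generate_tissue_map(p)
  expect_true(all(tm$pixels == fine_class_legend()[["background"]]))
})

test_that("tissue generation is deterministic and fraction-accurate", {
  p <- small_params(seed = 42)
  expect_identical(
    generate_tissue_map(p)$pixels,
    generate_tissue_map(p)$pixels
  )

  frac <- c(invasive_tumor = 0.3, tumor_assoc_stroma = 0.4, background = 0.3)
  emp <- sapply(1:20, function(s) {
    p <- synth_params(
      width = 1024, height = 1024, class_fractions = frac,
      lympho_rate = c(
        invasive_tumor = 0, tumor_assoc_stroma = 0,
        background = 0
      ), seed = s
    )
    tm <- generate_tissue_map(p)
    lg <- fine_class_legend()
    vapply(
      names(frac),
      function(cl) mean(tm$pixels == lg[[cl]]), numeric(1)
    )
  })
  expect_true(all(abs(rowMeans(emp) - frac) < 0.05))
})

test_that("tissue regions are contiguous blobs, not pixel noise", {
  p <- small_params(seed = 5)
  tm <- generate_tissue_map(p)
  # neighbouring pixels agree far more often than under a random shuffle
  same_right <- mean(tm$pixels[, -1] == tm$pixels[, -ncol(tm$pixels)])
  expect_gt(same_right, 0.9)
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_params(width = 0), "positive")
  expect_error(
    synth_params(class_fractions = c(background = 0.5)),
    "sum to 1"
  )
  expect_error(
    synth_params(lympho_rate = c(background = -1)),
    ">= 0"
  )
})

test_that("point sampling is deterministic, empty at zero rate, Poisson in mean", {
  p <- small_params(seed = 9)
  tm <- generate_tissue_map(p)
  expect_identical(
    sample_lymphocyte_points(tm, p),
    sample_lymphocyte_points(tm, p)
  )

  p0 <- small_params(seed = 9)
  p0$lympho_rate[] <- 0
  expect_identical(nrow(sample_lymphocyte_points(tm, p0)), 0L)

  # single class, rate r, no hard core: mean count over 200 seeds ~ r * A
  rate <- 0.01
  counts <- vapply(1:200, function(s) {
    p1 <- synth_params(
      width = 64, height = 64,
      class_fractions = c(inflamed_stroma = 1),
      lympho_rate = c(inflamed_stroma = rate),
      min_separation = 0, seed = s
    )
    nrow(sample_lymphocyte_points(generate_tissue_map(p1), p1))
  }, numeric(1))
  lambda <- rate * 64 * 64
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})

test_that("a rate map missing a present class is an error", {
  p <- small_params(seed = 2)
  tm <- generate_tissue_map(p)
  p$lympho_rate <- p$lympho_rate[setdiff(names(p$lympho_rate), "inflamed_stroma")]
  expect_error(sample_lymphocyte_points(tm, p), "missing class")
})

test_that("hard-core thinning enforces the minimum separation", {
  for (s in 1:5) {
    p <- small_params(seed = s, min_separation = 12)
    pts <- sample_lymphocyte_points(generate_tissue_map(p), p)
    if (nrow(pts) > 1) {
      d <- dist(cbind(pts$x, pts$y))
      expect_gte(min(d), 12)
    }
  }
})

test_that("noise-free maps reproduce the ground truth exactly", {
  p <- small_params(seed = 4, noise_sigma = 0, blur_radius = 0)
  tm <- generate_tissue_map(p)
  pts <- sample_lymphocyte_points(tm, p)
  maps <- render_probability_maps(tm, pts, p)

  expect_identical(seg_argmax(maps$seg), merge_classes(tm))
  expect_true(all(abs(apply(maps$seg, c(1, 2), sum) - 1) < 1e-6))

  expected <- matrix(0, 128, 128)
  expected[cbind(pts$y + 1, pts$x + 1)] <- 1
  expect_identical(maps$det, expected)
})

test_that("probability channels stay normalized under noise", {
  p <- small_params(seed = 6, noise_sigma = 0.4)
  tm <- generate_tissue_map(p)
  pts <- sample_lymphocyte_points(tm, p)
  maps <- render_probability_maps(tm, pts, p)
  sums <- maps$seg[, , 1] + maps$seg[, , 2] + maps$seg[, , 3]
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(maps$seg >= 0))
  expect_true(all(maps$det >= 0 & maps$det <= 1))
})

test_that("segmentation Dice degrades monotonically with noise", {
  sigmas <- c(0, 0.1, 0.3, 0.6)
  mean_dice <- vapply(sigmas, function(sig) {
    mean(vapply(1:20, function(s) {
      p <- small_params(seed = 300 + s, noise_sigma = sig)
      tm <- generate_tissue_map(p)
      maps <- render_probability_maps(tm, data.frame(x = integer(0), y = integer(0)), p)
      per_class_dice(seg_argmax(maps$seg), merge_classes(tm))[["average"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) <= 0))
})

test_that("annotation boxes follow the centering convention", {
  coco <- emit_annotations(data.frame(x = 100, y = 50), box_side = 12)
  expect_equal(coco$annotations[[1]]$bbox, c(94, 44, 12, 12))
  expect_length(emit_annotations(data.frame(x = numeric(0), y = numeric(0)))$annotations, 0)
})

test_that("points -> annotations -> mask -> centroids round-trips within 1 px", {
  set.seed(77)
  # separation > box diagonal so rasterized boxes form distinct components
  raw <- data.frame(
    x = round(runif(60, 10, 245)),
    y = round(runif(60, 10, 245)), confidence = runif(60)
  )
  keep <- ref_nms(raw, 20)
  pts <- keep[order(keep$y, keep$x), c("x", "y")]
  rownames(pts) <- NULL
  coco <- emit_annotations(pts, box_side = 12)
  mask <- boxes_to_mask(coco, c(256, 256), box_side = 12)
  cen <- component_centroids(label_components(mask))
  cen <- cen[order(cen$y, cen$x), ]
  expect_equal(nrow(cen), nrow(pts))
  expect_true(all(abs(cen$x - pts$x) <= 1))
  expect_true(all(abs(cen$y - pts$y) <= 1))
})

test_that("cohorts carry manifests and reference scores", {
  dir1 <- tempfile("cohort1_")
  p <- small_params(seed = 21)
  m1 <- generate_cohort(1, p, dir1, tile_side = 128)
  expect_equal(nrow(m1$manifest), 1)
  sc1 <- read_scores(file.path(dir1, "til-scores.csv"))
  expect_equal(nrow(sc1), 1)
  expect_false(is.na(sc1$til_score))

  # a stroma-free slide gets an undefined reference score
  dir2 <- tempfile("cohort2_")
  p2 <- synth_params(
    width = 96, height = 96,
    class_fractions = c(invasive_tumor = 0.6, background = 0.4),
    lympho_rate = c(invasive_tumor = 1e-3, background = 0),
    seed = 8
  )
  m2 <- suppressWarnings(generate_cohort(1, p2, dir2))
  expect_true(is.na(m2$scores$til_score))

  # a full-size cohort: one row per slide, defined scores within [0, 100]
  dir3 <- tempfile("cohort3_")
  p3 <- small_params(seed = 13)
  p3$width <- 256L
  p3$height <- 256L
  m3 <- suppressWarnings(generate_cohort(82, p3, dir3))
  sc <- read_scores(file.path(dir3, "til-scores.csv"))
  expect_equal(nrow(sc), 82)
  ok <- !is.na(sc$til_score)
  expect_true(all(sc$til_score[ok] >= 0 & sc$til_score[ok] <= 100))
  unlink(c(dir1, dir2, dir3), recursive = TRUE)
})
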