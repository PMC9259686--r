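test_that("pixel metrics match hand-counted toy cases", {
  # identical nonempty masks -> all ones
  m <- matrix(0L, 4, 4); m[2:3, 2:3] <- 1L
  r <- pixel_metrics(m, m)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 1)
  expect_equal(r$iou, 1)

  # disjoint nonempty masks -> all zeros
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  r <- pixel_metrics(a, b)
  expect_equal(c(r$precision, r$recall, r$f1, r$iou), c(0, 0, 0, 0))

  # tp=2 fp=1 fn=1 -> p = r = f1 = 2/3, iou = 1/2
  pred <- matrix(0L, 4, 4); pred[1, 1:3] <- 1L
  gt <- matrix(0L, 4, 4); gt[1, 1:2] <- 1L; gt[2, 1] <- 1L
  r <- pixel_metrics(pred, gt)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  expect_equal(r$iou, 0.5)
})

test_that("undefined metrics are flagged NA, never silently zero", {
  empty <- matrix(0L, 4, 4)
  r <- pixel_metrics(empty, empty)
  expect_true(is.na(r$precision))
  expect_true(is.na(r$recall))
  expect_true(is.na(r$iou))
  # no positives predicted but positives exist: precision undefined, recall 0
  gt <- matrix(0L, 4, 4); gt[1, 1] <- 1L
  r <- pixel_metrics(empty, gt)
  expect_true(is.na(r$precision))
  expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)
})

test_that("pixel metrics agree with a brute-force counting oracle on random masks", {
  set.seed(101)
  for (i in 1:60) {
    p <- random_mask(7, 9, runif(1, 0.1, 0.9))
    g <- random_mask(7, 9, runif(1, 0.1, 0.9))
    r <- pixel_metrics(p, g)
    o <- oracle_pixel_counts(as.vector(p), as.vector(g))
    expect_identical(r$counts$tp, o$tp)
    expect_identical(r$counts$fp, o$fp)
    expect_identical(r$counts$fn, o$fn)
    if (o$tp + o$fp > 0) expect_equal(r$precision, o$tp / (o$tp + o$fp))
    if (o$tp + o$fp + o$fn > 0)
      expect_equal(r$iou, o$tp / (o$tp + o$fp + o$fn))
  }
})

test_that("image-level F1 follows the confusion-count formula", {
  expect_equal(image_level_f1(c("artifact", "clean"), c("artifact", "clean"))$f1, 1)
  # all predicted clean with true artifacts -> recall 0, f1 0
  r <- image_level_f1(rep("clean", 4), c("artifact", "clean", "artifact", "clean"))
  expect_equal(r$recall, 0)
  expect_equal(r$f1, 0)
  # tp=4 fp=1 fn=1 in 10 images -> f1 = 0.8
  truth <- c(rep("artifact", 5), rep("clean", 5))
  pred <- c(rep("artifact", 4), "clean", "artifact", rep("clean", 4))
  expect_equal(image_level_f1(pred, truth)$f1, 0.8)
  expect_error(image_level_f1("bogus", "clean"), "clean")
})

test_that("object F1 matches constructed-rectangle cases", {
  # identical 3-object masks -> f1 = 1
  m <- matrix(0L, 12, 12)
  m[1:2, 1:2] <- 1L; m[5:6, 5:7] <- 1L; m[10:12, 1:2] <- 1L
  expect_equal(object_f1(m, m)$f1, 1)

  # single pair at IoU 0.4 with threshold 0.5 -> tp = 0
  p <- matrix(0L, 10, 10); p[1:2, 1:5] <- 1L        # 10 px
  g <- matrix(0L, 10, 10); g[1:2, 3:7] <- 1L        # 10 px, overlap 6 -> IoU 6/14
  expect_lt(6 / 14, 0.5)
  r <- object_f1(p, g, iou_threshold = 0.5)
  expect_equal(r$counts$tp, 0L)
  expect_equal(r$f1, 0)
  # same pair passes at a lower threshold
  expect_equal(object_f1(p, g, iou_threshold = 0.4)$f1, 1)

  # empty prediction, 2 true objects -> recall 0, fn = 2
  g2 <- matrix(0L, 8, 8); g2[1, 1] <- 1L; g2[8, 8] <- 1L
  r <- object_f1(matrix(0L, 8, 8), g2)
  expect_equal(r$recall, 0)
  expect_equal(r$counts$fn, 2L)
})

test_that("object F1 is invariant to component label permutation", {
  set.seed(7)
  p <- random_mask(15, 15, 0.25)
  g <- random_mask(15, 15, 0.25)
  r1 <- object_f1(p, g)
  # flipping both masks permutes the raster-order labels of all components
  r2 <- object_f1(p[15:1, 15:1], g[15:1, 15:1])
  expect_equal(r1$f1, r2$f1)
  expect_identical(r1$counts, r2$counts)
})

test_that("PR curve is exact on a perfect score map and monotone in recall", {
  gt <- matrix(0L, 20, 20); gt[5:10, 5:10] <- 1L
  res <- pr_curve(list(gt * 1.0), list(gt), thresholds = seq(0.1, 0.9, 0.1))
  expect_true(all(res$curve$precision == 1))
  expect_true(all(res$curve$recall == 1))
  set.seed(11)
  sm <- matrix(runif(400), 20, 20)
  res2 <- pr_curve(list(sm), list(gt), thresholds = seq(0.05, 0.95, 0.05))
  expect_true(all(diff(res2$curve$recall) <= 1e-12))
})

test_that("random score maps give precision near pixel prevalence", {
  set.seed(42)
  q <- 0.3
  gts <- lapply(1:6, function(i) random_mask(100, 100, q))
  maps <- lapply(1:6, function(i) matrix(runif(1e4), 100, 100))
  res <- pr_curve(maps, gts, thresholds = seq(0.1, 0.8, 0.1))
  prev <- mean(unlist(gts))
  expect_true(all(abs(res$curve$precision - prev) < 0.02))
})

test_that("aggregation averages per image and skips undefined entries", {
  m1 <- matrix(0L, 4, 4); m1[1:2, 1:2] <- 1L
  r_perfect <- pixel_metrics(m1, m1)                 # all ones
  r_undef <- pixel_metrics(matrix(0L, 4, 4), matrix(0L, 4, 4))
  agg <- aggregate_metrics(list(r_perfect, r_undef))
  expect_equal(unname(agg$per_image_mean["iou"]), 1)  # NA skipped
  expect_equal(agg$pooled$counts$tp, 4)
})
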