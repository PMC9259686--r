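test_that("plateau schedule reduces the rate tenfold after the patience window", {
  # validation loss never improves after epoch 1
  losses <- c(1.0, rep(1.5, 20))
  lrs <- lr_schedule(losses, initial_lr = 0.002, factor = 10, patience = 10)
  # epochs 2..11 stagnate; the reduction takes effect at epoch 12
  expect_equal(lrs[11], 0.002)
  expect_equal(lrs[12], 0.0002)
  # second window: epochs 12..21 stagnate -> 2e-5 at epoch 22
  expect_equal(lrs[22], 2e-5)
  expect_true(all(diff(lrs) <= 0))
})

test_that("improvements reset the stagnation counter", {
  losses <- c(1.0, rep(1.5, 9), 0.9, rep(1.5, 9))
  lrs <- lr_schedule(losses, 0.002, 10, 10)
  expect_equal(lrs[length(lrs)], 0.002)              # never 10 stale in a row
})

test_that("scorecam core equals the hand-computed weighted ReLU sum", {
  # K = 2 known 4x4 maps, stub scorer with fixed weights 0.8 and 0.1
  set.seed(2)
  a1 <- matrix(runif(16), 4, 4)
  a2 <- matrix(runif(16), 4, 4)
  stack <- array(c(a1, a2), c(4, 4, 2))
  input <- matrix(runif(64, 0.2, 0.8), 8, 8)
  scorer <- function(projected) c(0.8, 0.1)
  out <- artseg:::scorecam_from_stack(stack, input, scorer)

  # independent per-pixel oracle
  up_norm <- function(a) {
    u <- resize_bilinear(a, 8, 8)
    (u - min(u)) / (max(u) - min(u))
  }
  s <- 0.8 * up_norm(a1) + 0.1 * up_norm(a2)
  s <- pmax(s, 0)
  s <- (s - min(s)) / (max(s) - min(s))
  expect_equal(out, s, tolerance = 1e-12)
  expect_equal(dim(out), dim(input))
})

test_that("scorecam of an all-zero activation stack is all zeros", {
  stack <- array(0, c(4, 4, 3))
  input <- matrix(runif(36), 6, 6)
  out <- artseg:::scorecam_from_stack(stack, input, function(p) c(1, 1, 1))
  expect_true(all(out == 0))
})

test_that("scorecam is invariant to activation-map order", {
  set.seed(3)
  maps <- lapply(1:3, function(i) matrix(runif(16), 4, 4))
  input <- matrix(runif(64), 8, 8)
  w <- c(0.7, 0.2, 0.4)
  out1 <- artseg:::scorecam_from_stack(array(unlist(maps), c(4, 4, 3)),
                                       input, function(p) w)
  perm <- c(3, 1, 2)
  out2 <- artseg:::scorecam_from_stack(array(unlist(maps[perm]), c(4, 4, 3)),
                                       input, function(p) w[perm])
  expect_equal(out1, out2, tolerance = 1e-12)
})

test_that("binarization is strict and count-exact", {
  expect_equal(sum(binarize_map(matrix(0, 3, 3), 0.05)), 0)
  m <- matrix(c(0, 0.04, 0.05, 0.06, 0.2, 0.5, 1, 0.049, 0.051), 3, 3)
  out <- binarize_map(m, 0.05)
  expect_equal(sum(out), sum(m > 0.05))              # strict inequality
  expect_equal(out[m == 0.05], 0L)
  expect_error(binarize_map(m, 1.5), "0,1")
})

test_that("threshold selection matches the exhaustive sweep and tie-breaks low", {
  # perfect 0/1 map: every threshold ties at IoU 1 -> smallest returned
  gt <- matrix(0L, 6, 6); gt[2:4, 2:4] <- 1L
  sel <- select_threshold(list(gt * 1.0), list(gt), grid = c(0.25, 0.5, 0.75))
  expect_equal(sel$threshold, 0.25)
  expect_true(all(sel$table$mean_iou == 1))

  set.seed(13)
  for (i in 1:25) {
    maps <- lapply(1:4, function(j) matrix(runif(64), 8, 8))
    gts <- lapply(1:4, function(j) random_mask(8, 8, runif(1, 0.2, 0.7)))
    grid <- sort(runif(6))
    sel <- select_threshold(maps, gts, grid)
    ref <- oracle_threshold_sweep(maps, gts, grid)
    expect_equal(sel$table$mean_iou, ref, tolerance = 1e-12)
    expect_equal(sel$threshold, grid[which.max(ref)])
  }
})

test_that("the published pseudo-label operating point is in the default grid", {
  expect_true(0.05 %in% artseg:::default_threshold_grid())
  expect_true(0.001 %in% artseg:::default_threshold_grid())
})

test_that("classifier trains to high accuracy on a separable toy problem", {
  toy <- toy_classif_data(20, 32, seed = 5)
  idx_tr <- c(1:14, 21:34)
  idx_va <- setdiff(seq_along(toy$labels), idx_tr)
  cfg <- classifier_config("small", input_size = 32, seed = 2)
  tc <- train_config(epochs = 8, lr_patience_epochs = 4, batch_size = 8)
  clf <- train_classifier(list(train = list(images = toy$images[idx_tr],
                                            labels = toy$labels[idx_tr]),
                               val = list(images = toy$images[idx_va],
                                          labels = toy$labels[idx_va])),
                          cfg, tc)
  # history contract
  expect_lte(nrow(clf$history), tc$epochs)
  expect_true(all(diff(clf$history$lr) <= 0))
  # training accuracy
  pr <- classify(clf, toy$images[idx_tr])
  acc <- mean(ifelse(pr[, "artifact"] > 0.5, "artifact", "clean") ==
                toy$labels[idx_tr])
  expect_gte(acc, 0.95)
  # held-out F1
  prv <- classify(clf, toy$images[idx_va])
  predv <- ifelse(prv[, "artifact"] > 0.5, "artifact", "clean")
  expect_gte(image_level_f1(predv, toy$labels[idx_va])$f1, 0.9)
  # probabilities normalize and inference is deterministic
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  expect_identical(classify(clf, toy$images[[1]]),
                   classify(clf, toy$images[[1]]))
  # saliency map contract on a toy artifact image
  sal <- scorecam_map(clf, toy$images[[30]])
  expect_equal(dim(sal), dim(toy$images[[30]]))
  expect_gte(min(sal), 0)
  expect_lte(max(sal), 1)
})

test_that("single-class training data is rejected", {
  toy <- toy_classif_data(4, 32, seed = 1)
  clean_only <- which(toy$labels == "clean")
  expect_error(
    train_classifier(list(train = list(images = toy$images[clean_only],
                                       labels = toy$labels[clean_only]),
                          val = list(images = toy$images[1:2],
                                     labels = toy$labels[1:2])),
                     classifier_config("small", input_size = 32),
                     train_config(epochs = 2, lr_patience_epochs = 1)),
    "both classes")
})

test_that("pseudo-labels: clean images get zero masks, artifact images binarized maps", {
  toy <- toy_classif_data(6, 32, seed = 8)
  idx_tr <- c(1:4, 7:10)
  idx_va <- setdiff(seq_along(toy$labels), idx_tr)
  clf <- train_classifier(list(train = list(images = toy$images[idx_tr],
                                            labels = toy$labels[idx_tr]),
                               val = list(images = toy$images[idx_va],
                                          labels = toy$labels[idx_va])),
                          classifier_config("small", input_size = 32, seed = 4),
                          train_config(epochs = 2, lr_patience_epochs = 1,
                                       batch_size = 4))
  masks <- make_pseudolabels(clf, toy$images, toy$labels, threshold = 0.05)
  expect_length(masks, length(toy$images))
  for (i in seq_along(masks)) {
    if (toy$labels[i] == "clean") {
      expect_equal(sum(masks[[i]]), 0)
    } else {
      ref <- binarize_map(scorecam_map(clf, toy$images[[i]]), 0.05)
      expect_identical(masks[[i]], ref)
    }
  }
  expect_error(make_pseudolabels(clf, toy$images[1:2], c("clean", "weird")),
               "clean")
})
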