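test_that("fusion reproduces the loop-level combination rule exactly", {
  set.seed(61)
  for (rep in 1:20) {
    K <- sample(c(3, 5, 10), 1)
    members <- random_ensemble(K)
    fus <- fuse_ensemble(members)
    oracle <- fuse_oracle(members)
    expect_equal(fus$weights, oracle$weights, tolerance = 1e-12)
    expect_equal(fus$counts, oracle$counts)
    expect_identical(as.vector(fus$fused$data), oracle$fused)
    expect_equal(sum(fus$weights), 1, tolerance = 1e-12)
    expect_equal(fus$corr, t(fus$corr))
  }
})

test_that("identical members share the weight and threshold the member", {
  m <- random_ensemble(1)[[1]]
  members <- replicate(6, m, simplify = FALSE)
  fus <- fuse_ensemble(members)
  expect_equal(fus$weights, rep(1 / 6, 6))
  expect_identical(fus$fused$data, array(as.integer(m$data >= 0.5),
                                         dim(m$data)))
})

test_that("an anti-correlated outlier member is down-weighted", {
  set.seed(62)
  base <- array(runif(8^3), c(8, 8, 8))
  members <- lapply(1:9, function(i)
    ct_volume(pmin(pmax(base + rnorm(8^3, 0, 0.05), 0), 1)))
  members[[10]] <- ct_volume(1 - base)
  fus <- fuse_ensemble(members)
  expect_lt(fus$weights[10], 1 / 10)
  expect_gt(min(fus$weights[1:9]), fus$weights[10])
  oracle <- fuse_oracle(members)
  expect_equal(fus$weights, oracle$weights, tolerance = 1e-12)
})

test_that("fusion is invariant to member ordering", {
  set.seed(63)
  members <- random_ensemble(7)
  perm <- sample(7)
  a <- fuse_ensemble(members)
  b <- fuse_ensemble(members[perm])
  expect_equal(b$weights, a$weights[perm], tolerance = 1e-12)
  expect_identical(a$fused$data, b$fused$data)
})

test_that("uniformly high correlations reduce fusion to the plain mean", {
  set.seed(64)
  base <- array(runif(8^3), c(8, 8, 8))
  members <- lapply(1:5, function(i)
    ct_volume(pmin(pmax(base + rnorm(8^3, 0, 0.01), 0), 1)))
  fus <- fuse_ensemble(members)
  offdiag <- fus$corr[upper.tri(fus$corr)]
  expect_true(all(offdiag > 0.8))
  expect_equal(fus$counts, rep(5, 5))
  plain_mean <- Reduce(`+`, lapply(members, function(m) m$data)) / 5
  expect_identical(fus$fused$data,
                   array(as.integer(plain_mean >= 0.5), dim(plain_mean)))
})

test_that("zero-variance members are excluded with a warning", {
  set.seed(65)
  members <- random_ensemble(4)
  members[[2]] <- ct_volume(array(0.3, c(8, 8, 8)))
  expect_warning(fus <- fuse_ensemble(members), "zero variance")
  expect_equal(fus$weights[2], 0)
  expect_equal(sum(fus$weights), 1)
  # all members degenerate: nothing to fuse
  flat <- replicate(3, ct_volume(array(0.3, c(8, 8, 8))), simplify = FALSE)
  expect_error(suppressWarnings(fuse_ensemble(flat)), "no valid")
  expect_error(fuse_ensemble(list(members[[1]])), ">= 2")
})

seg_toy_pairs <- function(n = 2, seed = 70) {
  co <- make_cohort(n, seed = seed, random_pose = FALSE, noise_sd = 4)
  lapply(co$pairs, function(ph) {
    den <- denoise_nlm(ph$ct)
    z <- zscore_brain(den, ctquant:::phantom_brain_mask(ph))
    list(ct = z, labels = segmentation_classes(ph$labels))
  })
}

test_that("training is deterministic and its loss decreases", {
  pairs <- fixture("seg_pairs_small", function() seg_toy_pairs(2))
  cfg <- segmenter_config(epochs = 6, seed = 5L)
  m1 <- fixture("seg_model_small", function() train_segmenter(pairs, cfg))
  m2 <- train_segmenter(pairs, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$stem$W, m2$stem$W)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
})

test_that("predictions are voxelwise probability distributions", {
  pairs <- fixture("seg_pairs_small", function() seg_toy_pairs(2))
  m <- fixture("seg_model_small", function()
    train_segmenter(pairs, segmenter_config(epochs = 6, seed = 5L)))
  p <- predict_segmenter(m, pairs[[1]]$ct)
  tot <- p$background$data + p$csf$data + p$wml$data
  expect_equal(tot, array(1, dim(tot)), tolerance = 1e-9)
  expect_true(all(p$csf$data >= 0 & p$csf$data <= 1))
  # raw (tilted) posterior also sums to 1
  praw <- predict_segmenter(m, pairs[[1]]$ct, unbias = FALSE)
  tot2 <- praw$background$data + praw$csf$data + praw$wml$data
  expect_equal(tot2, array(1, dim(tot2)), tolerance = 1e-9)
})

test_that("a missing class zeroes its loss weight with a warning", {
  pairs <- fixture("seg_pairs_small", function() seg_toy_pairs(2))
  nowml <- lapply(pairs, function(p) {
    lab <- p$labels
    lab$data[lab$data == 2L] <- 0L
    list(ct = p$ct, labels = lab)
  })
  expect_warning(
    m <- train_segmenter(nowml, segmenter_config(epochs = 1)),
    "absent")
  expect_equal(m$class_weights[3], 0)
})

test_that("ensemble members differ across seeds and K is enforced", {
  pairs <- fixture("seg_pairs_small", function() seg_toy_pairs(2))
  ens <- train_ensemble(pairs, K = 2,
                        config = segmenter_config(epochs = 2))
  expect_length(ens, 2)
  expect_false(identical(ens[[1]]$stem$W, ens[[2]]$stem$W))
  preds <- predict_ensemble(ens, pairs[[1]]$ct)
  expect_length(preds$csf, 2)
  expect_false(identical(preds$csf[[1]]$data, preds$csf[[2]]$data))
  expect_error(train_ensemble(pairs, K = 1), ">= 2")
  expect_error(predict_ensemble(ens[1], pairs[[1]]$ct), ">= 2")
})

test_that("training overfits a small cohort to high CSF Dice", {
  pairs <- fixture("seg_pairs_overfit", function() seg_toy_pairs(3, seed = 71))
  m <- train_segmenter(pairs, segmenter_config(epochs = 60, seed = 2L))
  dices <- sapply(pairs, function(p) {
    pr <- predict_segmenter(m, p$ct)
    dice(pr$csf$data > 0.5, p$labels$data == 1L)
  })
  expect_gt(min(dices), 0.8)
})

test_that("cross-validation partitions the cohort exactly once", {
  pairs <- fixture("seg_pairs_cv", function() {
    co <- make_cohort(10, seed = 72, random_pose = FALSE, noise_sd = 4,
                      grid_shape = c(32, 32, 32), voxel_size_mm = 5)
    lapply(co$pairs, function(ph) {
      z <- zscore_brain(ph$ct, ctquant:::phantom_brain_mask(ph))
      list(ct = z, labels = segmentation_classes(ph$labels))
    })
  })
  cfg <- segmenter_config(epochs = 1, base_channels = 2, patch_size = 16)
  cv <- crossvalidate(pairs, folds = 10, config = cfg, seed = 9)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_equal(as.vector(table(cv$fold)), rep(1, 10))
  expect_true(all(!vapply(cv$predictions, is.null, TRUE)))
  cv2 <- crossvalidate(pairs, folds = 5, config = cfg, seed = 9)
  expect_equal(as.vector(table(cv2$fold)), rep(2, 5))
  expect_error(crossvalidate(pairs, folds = 11, config = cfg), "exceed")
})
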