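# Confusion metrics against a brute-force per-pixel oracle and the
# threshold sweep contract.

test_that("confusion counts are exact", {
  gt <- array(0, c(1, 64, 64)); gt[1, 1:10, 1:10] <- 1
  cc <- confusion_counts(gt, gt)
  expect_equal(cc, c(TP = 100, FP = 0, FN = 0, TN = 3996))
  all1 <- array(1, c(1, 8, 8)); all0 <- array(0, c(1, 8, 8))
  expect_equal(confusion_counts(all1, all0)[["FP"]], 64)
  expect_error(confusion_counts(all1 * 0.5, all0), "binary")
})

test_that("metrics from counts equal brute-force recomputation", {
  set.seed(20)
  for (i in 1:10) {
    pred <- matrix(rbinom(64, 1, 0.4), 8, 8)
    gt <- matrix(rbinom(64, 1, 0.3), 8, 8)
    cc <- confusion_counts(pred, gt)
    # brute-force per-pixel tally
    tally <- table(factor(paste0(pred, gt), levels = c("11", "10", "01", "00")))
    expect_equal(unname(cc), as.vector(unname(tally)))
    rep <- seg_metrics(cc)
    tp <- sum(pred & gt); fp <- sum(pred & !gt); fn <- sum(!pred & gt)
    if (tp + fp + fn > 0) {
      expect_equal(rep$root[["iou"]], tp / (tp + fp + fn))
    }
    expect_equal(rep$root[["f1"]],
                 if (rep$root[["precision"]] + rep$root[["recall"]] == 0) 0 else
                   2 * rep$root[["precision"]] * rep$root[["recall"]] /
                   (rep$root[["precision"]] + rep$root[["recall"]]))
    # means are unweighted two-class averages
    expect_equal(rep$mean, (rep$root + rep$background) / 2)
  }
})

test_that("metric formulas reproduce direct arithmetic and degenerate rules", {
  rep <- seg_metrics(c(TP = 50, FP = 25, FN = 25, TN = 100))
  expect_equal(rep$root[["iou"]], 0.5)
  expect_equal(rep$root[["precision"]], 2 / 3)
  expect_equal(rep$root[["recall"]], 2 / 3)
  expect_equal(rep$root[["f1"]], 2 / 3)
  perfect <- seg_metrics(c(TP = 10, FP = 0, FN = 0, TN = 90))
  expect_true(all(unlist(perfect[c("root", "background", "mean")]) == 1))
  # TP = 0 with errors present -> zeros, not NaN
  zr <- seg_metrics(c(TP = 0, FP = 5, FN = 5, TN = 90))
  expect_equal(zr$root[["iou"]], 0)
  expect_equal(zr$root[["f1"]], 0)
  # empty-empty agreement counts as perfect for the root class
  ee <- seg_metrics(c(TP = 0, FP = 0, FN = 0, TN = 64))
  expect_equal(ee$root[["iou"]], 1)
})

test_that("threshold sweep evaluates 9 thresholds and returns the argmax", {
  set.seed(21)
  probs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  gts <- lapply(probs, function(p) (p > 0.5) * 1)
  sw <- threshold_sweep(probs, gts)
  expect_length(sw$miou, 9L)
  # brute-force argmax check
  brute <- vapply(seq(0.1, 0.9, 0.1), function(th) {
    acc <- c(TP = 0, FP = 0, FN = 0, TN = 0)
    for (j in seq_along(probs))
      acc <- acc + confusion_counts((probs[[j]] >= th) * 1, gts[[j]])
    seg_metrics(acc)$mean[["iou"]]
  }, numeric(1))
  expect_equal(unname(sw$miou), brute)
  expect_equal(sw$threshold, seq(0.1, 0.9, 0.1)[which.max(brute)])
  # ground truth cut at 0.5 -> 0.5 is optimal (up to grid equality)
  expect_equal(max(sw$miou), sw$miou[["0.5"]])
  # binary probability maps tie everywhere -> smallest threshold returned
  bin <- lapply(gts, function(g) g)
  swb <- threshold_sweep(bin, gts)
  expect_equal(swb$threshold, 0.1)
  expect_equal(unname(swb$miou), rep(1, 9))
  expect_error(threshold_sweep(list(), list()), "empty")
})

test_that("TP is non-increasing in the threshold on a fixed map", {
  set.seed(22)
  p <- matrix(runif(400), 20, 20)
  g <- matrix(rbinom(400, 1, 0.3), 20, 20)
  tps <- vapply(seq(0.1, 0.9, 0.1), function(th)
    confusion_counts((p >= th) * 1, g)[["TP"]], numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("f1 excess ratio reproduces two-decimal truncation", {
  expect_equal(f1_excess_ratio(58.71, 25.28), 1.32)
  expect_equal(f1_excess_ratio(58.71, 23.94), 1.45)
  expect_equal(f1_excess_ratio(58.71, 25.91), 1.26)
  expect_equal(f1_excess_ratio(42, 42), 0)
  expect_error(f1_excess_ratio(10, 0), "zero")
})

test_that("micro mIoU is invariant to dataset ordering", {
  set.seed(23)
  probs <- lapply(1:5, function(i) matrix(runif(64), 8, 8))
  gts <- lapply(1:5, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
  a <- threshold_sweep(probs, gts)
  ord <- c(3, 5, 1, 2, 4)
  b <- threshold_sweep(probs[ord], gts[ord])
  expect_equal(a$miou, b$miou)
})
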