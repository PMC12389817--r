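# Skeleton lengths on constructed fixtures and agreement statistics
# against closed-form / cor.test oracles.

test_that("skeleton length measures constructed fixtures", {
  expect_equal(skeleton_length(matrix(0, 20, 20)), 0)
  # 100 x 3 horizontal bar: length within [99, 103]
  bar <- matrix(0, 13, 110); bar[6:8, 6:105] <- 1
  len <- skeleton_length(bar)
  expect_gte(len, 99); expect_lte(len, 103)
  # 45-degree stroke of 50 steps: ~50 * sqrt(2) within 5 %
  d <- matrix(0, 70, 70)
  for (i in 0:50) { d[10 + i, 10 + i] <- 1; d[11 + i, 10 + i] <- 1; d[10 + i, 11 + i] <- 1 }
  len2 <- skeleton_length(d)
  expect_lt(abs(len2 - 50 * sqrt(2)) / (50 * sqrt(2)), 0.05)
})

test_that("skeletonization yields thin masks and length is rigid-motion stable", {
  bar <- matrix(0, 40, 40); bar[18:21, 5:35] <- 1
  sk <- skeletonize_mask(bar)
  expect_true(all(rowSums(sk) <= diff(range(which(colSums(sk) > 0))) + 1))
  l0 <- skeleton_length(bar)
  # translation
  tr <- matrix(0, 40, 40); tr[10:13, 3:33] <- 1
  expect_lt(abs(skeleton_length(tr) - l0) / l0, 0.01)
  # 90-degree rotation
  expect_lt(abs(skeleton_length(t(bar)) - l0) / l0, 0.01)
})

test_that("pearson agreement matches the closed-form oracle", {
  set.seed(30)
  x <- rnorm(12); y <- 0.6 * x + rnorm(12, sd = 0.5)
  res <- pearson_agreement(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r_oracle * sqrt((12 - 2) / (1 - r_oracle^2))
  p_oracle <- 2 * stats::pt(-abs(tstat), df = 10)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)
  expect_equal(pearson_agreement(x, x)$r, 1)
  expect_error(pearson_agreement(x, rep(1, 12)), "variance")
  expect_error(pearson_agreement(x[1:2], y[1:2]), "at least 3")
})

test_that("agreement on the packaged length tables matches frozen oracles", {
  tb <- reference_root_lengths()
  expect_equal(nrow(tb$manual), 10L)
  expect_equal(nrow(tb$segmentation), 10L)
  expect_equal(tb$manual$order_1[1], 603)
  expect_equal(tb$manual$total_length[1], 1242)
  expect_equal(tb$segmentation$order_1[10], 1945)
  expect_equal(tb$segmentation$total_length[10], 8793)
  ag <- length_table_agreement(tb$manual, tb$segmentation)
  # frozen from stats::cor.test on the printed table (3 dp)
  expect_equal(round(ag$total_length$r, 3), 0.719)
  expect_equal(round(ag$order_1$r, 3), 0.270)
  expect_equal(round(ag$order_2$r, 3), -0.106)
  expect_equal(round(ag$order_3$r, 3), 0.880)
  expect_equal(round(ag$total_length$p_value, 3), 0.019)
  expect_equal(round(ag$order_1$p_value, 3), 0.451)
  expect_equal(round(ag$order_2$p_value, 3), 0.771)
  expect_lt(ag$order_3$p_value, 0.001)
  # only the strong third-order correlation survives Bonferroni (m = 4)
  expect_true(ag$order_3$significant_after_bonferroni)
  expect_false(ag$total_length$significant_after_bonferroni)
  expect_false(ag$order_1$significant_after_bonferroni)
})

test_that("r is invariant to affine rescaling (mm vs px units)", {
  tb <- reference_root_lengths()
  r0 <- pearson_agreement(tb$manual$total_length,
                          tb$segmentation$total_length)$r
  r1 <- pearson_agreement(tb$manual$total_length * 25.4 + 3,
                          tb$segmentation$total_length / 600)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("bonferroni flags compare against alpha / m", {
  expect_true(bonferroni_correct(c(0.01, 0.5, 0.5, 0.5))[1])   # 0.01 < 0.0125
  expect_false(bonferroni_correct(c(0.02, 0.5, 0.5, 0.5))[1])  # 0.02 > 0.0125
  expect_equal(bonferroni_correct(0.04), TRUE)                 # m = 1: p < alpha
  expect_error(bonferroni_correct(c(0.5, 1.2)), "0, 1")
})

test_that("length tables round-trip through CSV", {
  tb <- reference_root_lengths()$manual
  td <- withr::local_tempdir()
  p <- file.path(td, "t.csv")
  write_length_table(tb, p)
  expect_equal(read_length_table(p), tb)
  expect_error(read_length_table({
    q <- file.path(td, "bad.csv"); utils::write.csv(data.frame(a = 1), q); q
  }), "columns")
})
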