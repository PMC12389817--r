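# Mask binarization, sliding-window tiling, and the 7:2:1 split.

test_that("binarize_mask thresholds on the normalized scale and adds a channel", {
  m <- matrix(0, 4, 4)
  expect_equal(binarize_mask(m), array(0, c(1, 4, 4)))
  expect_equal(binarize_mask(matrix(255, 4, 4)), array(1, c(1, 4, 4)))
  # values {0, 100, 200} against 0.5 (127.5 on the 8-bit scale) -> {0, 0, 1}
  m <- matrix(c(0, 100, 200, 0), 2, 2)
  out <- binarize_mask(m, 0.5)
  expect_equal(dim(out), c(1, 2, 2))
  expect_equal(as.vector(out), c(0, 0, 1, 0))
  expect_error(binarize_mask(matrix(numeric(0), 0, 0)), "empty")
  # anti-aliased gray edges never pass through
  expect_true(is_binary <- all(binarize_mask(matrix(runif(16) * 255, 4)) %in% 0:1))
})

test_that("extract_patches covers the stated grid with black padding", {
  # the reference geometry: 1275 x 1755 at window 512 / stride 256 -> 4 x 6
  img <- array(0.5, c(1275, 1755, 3))
  ps <- extract_patches(img, patch = 512L, stride = 256L)
  expect_equal(length(ps), 24L)
  # 512 x 512 image -> exactly one patch, bit-identical (no padding)
  img2 <- random_rgb(512, 512)
  ps2 <- extract_patches(img2, patch = 512L, stride = 256L)
  expect_equal(length(ps2), 1L)
  expect_identical(ps2$patches[[1]]$image, img2)
  expect_error(extract_patches(array(0, c(0, 5, 3))), "1x1")
  expect_error(extract_patches(img2, patch = 128L, stride = 256L), "stride")
})

test_that("patch counts match the closed form against a brute-force enumerator", {
  brute_count <- function(n, P, s) {
    # slide until the window start passes the last pixel needed
    starts <- 0L
    while (utils::tail(starts, 1) + P < n) starts <- c(starts, utils::tail(starts, 1) + s)
    length(starts)
  }
  set.seed(42)
  for (i in 1:12) {
    H <- sample(5:60, 1); W <- sample(5:60, 1)
    P <- sample(4:16, 1); s <- sample.int(P, 1)
    ps <- extract_patches(array(0.1, c(H, W, 3)), patch = P, stride = s)
    expect_equal(length(ps),
                 (ceiling(max(H - P, 0) / s) + 1) * (ceiling(max(W - P, 0) / s) + 1))
    expect_equal(length(ps), brute_count(H, P, s) * brute_count(W, P, s))
  }
})

test_that("patches reconstruct the padded source bit-exactly", {
  img <- random_rgb(37, 53, seed = 7)
  msk <- rhizoseg:::with_seed(8, matrix(rbinom(37 * 53, 1, 0.1), 37, 53))
  ps <- extract_patches(img, msk, patch = 16L, stride = 8L, source_id = "t")
  rec <- reconstruct_from_patches(ps)
  expect_equal(rec[1:37, 1:53, ], img)
  expect_true(all(rec[38:nrow(rec), , ] == 0))   # padding is black
  # origins are multiples of the stride
  offs <- vapply(ps$patches, function(p) c(p$row, p$col), numeric(2))
  expect_true(all(offs %% 8 == 0))
})

test_that("split_dataset floors train/val and gives the remainder to test", {
  sp <- split_dataset(seq_len(1968), seed = 1L)
  expect_equal(lengths(sp[c("train", "val", "test")], use.names = FALSE),
               c(1377L, 393L, 198L))
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_len(1968))
  sp10 <- split_dataset(seq_len(10), seed = 3L)
  expect_equal(lengths(sp10[c("train", "val", "test")], use.names = FALSE),
               c(7L, 2L, 1L))
})

test_that("split_dataset is seed-reproducible and sizes are seed-invariant", {
  a <- split_dataset(seq_len(100), seed = 11L)
  b <- split_dataset(seq_len(100), seed = 11L)
  d <- split_dataset(seq_len(100), seed = 12L)
  expect_identical(a, b)
  expect_false(identical(a$train, d$train))
  expect_equal(lengths(a[1:3], use.names = FALSE), lengths(d[1:3], use.names = FALSE))
  expect_error(split_dataset(1:10, ratios = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(split_dataset(1:2), "at least 3")
})

test_that("pnm round-trip preserves images and patch files land on disk", {
  img <- round(random_rgb(9, 7) * 255) / 255
  td <- withr::local_tempdir()
  p <- file.path(td, "x.ppm")
  write_image(img, p)
  expect_equal(read_image(p), img, tolerance = 1 / 254)
  gray <- round(matrix(runif(35), 5, 7) * 255) / 255
  write_image(gray, file.path(td, "g.pgm"))
  expect_equal(read_image(file.path(td, "g.pgm")), gray, tolerance = 1 / 254)
  ps <- extract_patches(img, patch = 4L, stride = 4L, source_id = "s")
  paths <- write_patch_set(ps, td, ext = "png")
  expect_true(all(file.exists(paths)))
  expect_equal(dim(read_image(paths[1])), c(4, 4, 3))
})
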