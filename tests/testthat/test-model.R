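# Attention operators against hand-evaluated oracles, DoubleConv and
# forward-pass contracts, and the ablation grid.

test_that("channel attention matches the closed form on a small fixture", {
  set.seed(10)
  C <- 4L; r <- 2L
  f <- array(rnorm(C * 2 * 2), c(C, 2, 2))
  w1 <- matrix(rnorm(C * (C / r)), C, C / r); b1 <- rnorm(C / r)
  w2 <- matrix(rnorm((C / r) * C), C / r, C); b2 <- rnorm(C)
  mc <- channel_attention(f, w1, b1, w2, b2)
  # direct evaluation: shared MLP on the two pooled descriptors
  m <- matrix(f, C, 4)
  avg <- rowMeans(m); mx <- apply(m, 1, max)
  mlp <- function(v) drop(crossprod(w2, pmax(drop(crossprod(w1, v)) + b1, 0))) + b2
  expect_equal(mc, 1 / (1 + exp(-(mlp(avg) + mlp(mx)))), tolerance = 1e-12)
  expect_true(all(mc > 0 & mc < 1))
  # zero weights -> sigmoid(0) = 0.5 everywhere
  expect_equal(channel_attention(f, w1 * 0, b1 * 0, w2 * 0, b2 * 0),
               rep(0.5, C))
  # channel-symmetric input and weights -> equal weights
  fs <- array(1, c(C, 3, 3))
  expect_equal(length(unique(channel_attention(fs, w1, b1, w2, b2))), C)
  expect_equal(sd(channel_attention(fs, matrix(1, C, 2), c(0, 0),
                                    matrix(1, 2, C), rep(0, C))), 0)
})

test_that("spatial attention matches a hand-evaluated convolution", {
  # single hot pixel, identity-like kernel
  f <- array(0, c(1, 5, 5)); f[1, 3, 3] <- 4
  kern <- array(0, c(7, 7, 2, 1)); kern[4, 4, 2, 1] <- 1  # picks the max map
  ms <- spatial_attention(f, kern, bias = 0)
  expect_equal(dim(ms), c(1, 5, 5))
  expect_equal(ms[1, 3, 3], 1 / (1 + exp(-4)))
  expect_equal(ms[1, 1, 1], 0.5)
  # zero kernel -> uniform 0.5
  expect_true(all(spatial_attention(f, kern * 0) == 0.5))
  # spatially constant input -> constant map away from the padding margin
  fc <- array(2, c(3, 15, 15))
  k2 <- rhizoseg:::with_seed(2, array(rnorm(7 * 7 * 2), c(7, 7, 2, 1)))
  msc <- spatial_attention(fc, k2)
  expect_equal(sd(msc[1, 7:9, 7:9]), 0, tolerance = 1e-14)
})

test_that("cbam composition equals sequential sub-operations and is bounded", {
  set.seed(11)
  f <- array(rnorm(8 * 4 * 4), c(8, 4, 4))
  mlp <- list(w1 = matrix(rnorm(16), 8, 2), b1 = rnorm(2),
              w2 = matrix(rnorm(16), 2, 8), b2 = rnorm(8))
  kern <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  ref_mc <- channel_attention(f, mlp$w1, mlp$b1, mlp$w2, mlp$b2)
  ref_fp <- f * ref_mc
  ref_ms <- spatial_attention(ref_fp, kern, 0.3)
  got <- cbam_refine(f, mlp, kern, 0.3)
  expect_equal(got$out, ref_fp * ref_ms[rep(1, 8), , ], tolerance = 1e-12)
  expect_equal(got$channel, ref_mc)
  # gates in (0,1) bound the output magnitude element-wise
  expect_true(all(abs(got$out) <= abs(f)))
  # zero input stays zero
  z <- array(0, c(8, 4, 4))
  expect_true(all(cbam_refine(z, mlp, kern, 0)$out == 0))
})

test_that("unet_config validates the architecture contract", {
  expect_error(unet_config(stage_channels = c(64L, 100L)), "double")
  expect_error(unet_config(stage_channels = c(8L, 16L), reduction_ratio = 16L),
               "reduction_ratio")
  expect_error(unet_config(bottleneck_channels = 512L), "twice")
  cfg <- tiny_model_config()
  expect_equal(cfg$bottleneck_channels, 128L)
})

test_that("forward pass honours shapes, ranges, and encoder channel plan", {
  m <- unet_init(micro_model_config(), seed = 1)
  x <- rhizoseg:::with_seed(2, array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2)))
  p <- unet_forward(m, x)
  expect_equal(dim(p), c(1, 32, 32, 2))
  expect_true(all(p > 0 & p < 1))
  expect_error(unet_forward(m, array(0.5, c(3, 30, 30))), "divisible by 16")
  # encoder stage channels double and the bottleneck is 2x the last stage
  expect_equal(dim(m$params[["enc1.c1.w"]])[4], 4L)
  expect_equal(dim(m$params[["enc4.c2.w"]])[4], 32L)
  expect_equal(dim(m$params[["bott.c2.w"]])[4], 64L)
  expect_equal(dim(m$params[["head.w"]])[3:4], c(4L, 1L))
})

test_that("all six ablation configurations build and run forward", {
  x <- rhizoseg:::with_seed(3, array(runif(3 * 64 * 64), c(3, 64, 64)))
  for (att in c("none", "se", "cbam")) {
    for (fus in c("concat", "upadd")) {
      m <- unet_init(micro_model_config(att, fus), seed = 5)
      p <- unet_forward(m, x)
      expect_equal(dim(p), c(1, 64, 64, 1))
      expect_true(all(is.finite(p)))
    }
  }
})

test_that("concat fusion doubles the merged channel count (original U-Net)", {
  m <- unet_init(micro_model_config("none", "concat"), seed = 1)
  # decoder DoubleConv consumes 2C channels under concatenation
  expect_equal(dim(m$params[["dec1.dc.c1.w"]])[3], 8L)   # 2 x 4
  m2 <- unet_init(micro_model_config("none", "upadd"), seed = 1)
  expect_equal(dim(m2$params[["dec1.dc.c1.w"]])[3], 4L)  # additive: C
})

test_that("forward is permutation-equivariant across the batch", {
  m <- unet_init(micro_model_config(), seed = 2)
  x <- rhizoseg:::with_seed(4, array(runif(3 * 16 * 16 * 3), c(3, 16, 16, 3)))
  p <- unet_forward(m, x)
  xp <- x[, , , c(3, 1, 2), drop = FALSE]
  pp <- unet_forward(m, xp)
  expect_equal(pp, p[, , , c(3, 1, 2), drop = FALSE], tolerance = 1e-12)
})

test_that("inference mode is deterministic and training mode updates BN", {
  m <- unet_init(micro_model_config(), seed = 3)
  x <- rhizoseg:::with_seed(5, array(runif(3 * 16 * 16), c(3, 16, 16)))
  expect_identical(unet_forward(m, x), unet_forward(m, x))
  before <- m$bn[["enc1.bn1"]]$mean
  invisible(unet_forward(m, x, training = TRUE))
  expect_false(identical(before, m$bn[["enc1.bn1"]]$mean))
})

test_that("double conv preserves odd spatial sizes and is non-negative", {
  # exercise the internal block directly at several odd sizes
  for (hw in c(5L, 7L, 9L)) {
    tape <- rhizoseg:::ad_tape()
    x <- rhizoseg:::ad_input(tape, array(rnorm(3 * hw * hw), c(3, hw, hw, 1)))
    P <- list()
    P <- rhizoseg:::add_double_conv(P, "dc", 3L, 4L,
                                    unet_config(stage_channels = c(4L, 8L),
                                                bottleneck_channels = 16L,
                                                attention = "none"),
                                    attended = FALSE)
    bn <- new.env()
    bn[["dc.bn1"]] <- list(mean = numeric(4), var = rep(1, 4))
    bn[["dc.bn2"]] <- list(mean = numeric(4), var = rep(1, 4))
    pn <- lapply(P, function(v) rhizoseg:::ad_input(tape, v))
    cfg <- list(attention = "none")
    out <- rhizoseg:::fw_double_conv(x, "dc", pn, bn, cfg, training = TRUE)
    expect_equal(dim(out$value), c(4, hw, hw, 1))
    expect_true(all(out$value >= 0))
  }
})
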