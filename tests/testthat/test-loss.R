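# The hybrid loss components against hand-derived values, plus gradient
# finiteness and monotonicity properties.

test_that("dice loss reproduces hand-derived values", {
  # 4-pixel case: g = (1,1,0,0), p = 0.5 -> 1 - 2*1/(2+2) = 0.5 as smooth -> 0
  g <- c(1, 1, 0, 0)
  p <- rep(0.5, 4)
  expect_equal(dice_loss(p, g, smooth = 0), 0.5)
  # perfect binary prediction
  m <- array(0, c(1, 64, 64)); m[1, 10:19, 10:19] <- 1
  expect_lt(dice_loss(m, m, smooth = 1), 1e-3)
  expect_equal(dice_loss(m, m, smooth = 0), 0)
  # disjoint prediction -> 1
  g2 <- c(rep(1, 8), rep(0, 8))
  expect_equal(dice_loss(1 - g2, g2, smooth = 0), 1)
  expect_error(dice_loss(rep(0.5, 3), c(1, 0)), "differ")
  expect_error(dice_loss(c(1.2, 0), c(1, 0)), "0, 1")
})

test_that("focal loss matches the closed form and reduces to scaled BCE", {
  # single pixel, g = 1, p = 0.5: 0.9 * 0.5^2.5 * ln 2
  expect_equal(focal_loss(0.5, 1), 0.9 * 0.5^2.5 * log(2), tolerance = 1e-12)
  expect_equal(round(focal_loss(0.5, 1), 4), 0.1103)
  # g = 1, p -> 1 gives 0
  expect_lt(focal_loss(1 - 1e-9, 1), 1e-8)
  # gamma = 0, alpha = 0.5 is exactly half the mean BCE
  set.seed(1)
  p <- runif(50, 0.01, 0.99)
  g <- rbinom(50, 1, 0.4)
  expect_equal(focal_loss(p, g, focal_params(0.5, 0)),
               0.5 * mean(-(g * log(p) + (1 - g) * log(1 - p))),
               tolerance = 1e-9)
})

test_that("edge loss acts on the dilated Sobel band only", {
  # constant masks have no edges
  p <- matrix(0.3, 8, 8)
  expect_equal(edge_loss(p, matrix(0, 8, 8)), 0)
  expect_equal(edge_loss(p, matrix(1, 8, 8)), 0)
  # perfect prediction on a centered square
  g <- matrix(0, 16, 16); g[5:12, 5:12] <- 1
  expect_lt(edge_loss(g, g), 1e-6)
  # 1-px vertical line, p = 0.5 everywhere -> ln 2 over the band
  gl <- matrix(0, 8, 8); gl[, 4] <- 1
  expect_equal(edge_loss(matrix(0.5, 8, 8), gl), log(2), tolerance = 1e-12)
  # the band is the Sobel support dilated by 1
  eb <- edge_band(gl, dilate = 1L)
  expect_true(all(eb[, 2:6]))
  expect_false(any(eb[, c(1, 7, 8)]))
})

test_that("total loss combines components with the configured weights", {
  set.seed(2)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64, 0.05, 0.95), 8, 8)
  f <- focal_loss(p, g); d <- dice_loss(p, g); e <- edge_loss(p, g)
  expect_equal(total_loss(p, g), 0.4 * f + 0.4 * d + 0.2 * e)
  # components (1, 0, 0) with default weights -> 0.4 (weights sum to 1)
  expect_equal(sum(loss_weights()[1:3]), 1)
  # perfect binary prediction is near zero
  m <- array(0, c(1, 64, 64)); m[1, 20:30, 20:30] <- 1
  expect_lt(total_loss(m, m), 0.01)
})

test_that("all components are finite with finite gradients at the clamp", {
  g <- matrix(c(1, 0), 4, 4)
  for (pv in list(matrix(0, 4, 4), matrix(1, 4, 4), matrix(0.5, 4, 4))) {
    tl <- total_loss(pv, g, grad = TRUE)
    expect_true(is.finite(tl$value))
    expect_true(all(is.finite(tl$grad)))
    expect_true(all(vapply(list(focal_loss(pv, g), dice_loss(pv, g),
                                edge_loss(pv, g)), is.finite, logical(1))))
  }
})

test_that("analytic gradients match numeric differentiation", {
  set.seed(3)
  g <- matrix(rbinom(36, 1, 0.4), 6, 6)
  p <- matrix(runif(36, 0.1, 0.9), 6, 6)
  for (fn in list(function(p, gr) dice_loss(p, g, grad = gr),
                  function(p, gr) focal_loss(p, g, grad = gr),
                  function(p, gr) edge_loss(p, g, grad = gr),
                  function(p, gr) total_loss(p, g, grad = gr))) {
    res <- fn(p, TRUE)
    for (i in sample(36, 4)) {
      eps <- 1e-6
      p2 <- p; p2[i] <- p[i] + eps
      p3 <- p; p3[i] <- p[i] - eps
      v2 <- fn(p2, FALSE); v3 <- fn(p3, FALSE)
      if (is.list(v2)) { v2 <- v2$value; v3 <- v3$value }
      expect_equal(res$grad[i], (v2 - v3) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("moving p toward g decreases every component", {
  set.seed(4)
  g <- matrix(rbinom(64, 1, 0.3), 8, 8)
  far <- abs(g - 0.4)   # 0.4 / 0.6: wrong-leaning
  near <- abs(g - 0.1)  # 0.1 / 0.9: right-leaning
  expect_lt(dice_loss(near, g), dice_loss(far, g))
  expect_lt(focal_loss(near, g), focal_loss(far, g))
  expect_lt(edge_loss(near, g), edge_loss(far, g))
  expect_lt(total_loss(near, g), total_loss(far, g))
})
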