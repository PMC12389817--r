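# The hybrid segmentation loss: w1 * focal + w2 * Dice + w3 * edge.
#
# The focal term is the alpha-balanced focal generalization of binary
# cross-entropy (alpha = 0.9, gamma = 2.5 by default, emphasising the rare
# root class and hard pixels), the Dice term optimizes global overlap, and
# the edge term is plain BCE restricted to a 1-px-dilated Sobel band around
# ground-truth boundaries.  Every component can also return its gradient
# with respect to the probabilities, which is what the trainer backpropagates
# through the network's sigmoid head.

PROB_EPS <- 1e-7

#' Loss weights
#' @param w_focal,w_dice,w_edge Non-negative component weights; defaults
#'   0.4 / 0.4 / 0.2 (summing to 1).
#' @param w_bce Optional extra plain-BCE weight, default 0 (off).
#' @return Named numeric vector.
#' @export
loss_weights <- function(w_focal = 0.4, w_dice = 0.4, w_edge = 0.2,
                         w_bce = 0) {
  w <- c(focal = w_focal, dice = w_dice, edge = w_edge, bce = w_bce)
  if (any(w < 0)) stop_config("loss weights must be non-negative")
  w
}

#' Focal-loss parameters
#' @param alpha Class-balance weight on the positive (root) class, in (0,1).
#' @param gamma Focusing exponent, >= 0.
#' @return Named numeric vector.
#' @export
focal_params <- function(alpha = 0.9, gamma = 2.5) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (gamma < 0) stop_config("gamma must be >= 0")
  c(alpha = alpha, gamma = gamma)
}

check_pg <- function(p, g) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g)))
    stop_invalid("prediction and mask shapes differ")
  if (any(p < 0 | p > 1)) stop_invalid("probabilities must lie in [0, 1]")
  if (!is_binary(g)) stop_invalid("mask must be binary")
}

#' Dice loss
#'
#' `1 - (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)`, with the
#' sums taken jointly over all pixels supplied (global/batch Dice).
#'
#' @param p Probability array, values in `[0, 1]`.
#' @param g Binary mask of the same shape.
#' @param smooth Additive smoothing (default 1).
#' @param grad Also return the gradient with respect to `p`.
#' @return Scalar loss, or a list `(value, grad)`.
#' @export
dice_loss <- function(p, g, smooth = 1, grad = FALSE) {
  check_pg(p, g)
  num <- 2 * sum(p * g) + smooth
  den <- sum(p) + sum(g) + smooth
  val <- 1 - num / den
  if (!grad) return(val)
  list(value = val, grad = array(-(2 * g * den - num) / den^2, dim(p) %||% length(p)))
}

#' Focal loss
#'
#' Per-pixel `-alpha * (1-p)^gamma * log(p)` on root pixels and
#' `-(1-alpha) * p^gamma * log(1-p)` on background, averaged over all
#' pixels.  Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the
#' logarithms.  With `gamma = 0`, `alpha = 0.5` this is exactly half the
#' mean binary cross-entropy.
#'
#' @inheritParams dice_loss
#' @param params A [focal_params()] vector.
#' @return Scalar loss, or a list `(value, grad)`.
#' @export
focal_loss <- function(p, g, params = focal_params(), grad = FALSE) {
  check_pg(p, g)
  a <- params[["alpha"]]; gm <- params[["gamma"]]
  pc <- clamp(p, PROB_EPS, 1 - PROB_EPS)
  pos <- -a * (1 - pc)^gm * log(pc)
  neg <- -(1 - a) * pc^gm * log(1 - pc)
  val <- mean(g * pos + (1 - g) * neg)
  if (!grad) return(val)
  n <- length(p)
  dpos <- a * (gm * (1 - pc)^(gm - 1) * log(pc) - (1 - pc)^gm / pc)
  dneg <- -(1 - a) * (gm * pc^(gm - 1) * log(1 - pc) - pc^gm / (1 - pc))
  if (gm == 0) {  # 0 * Inf guards
    dpos <- a * (-1 / pc)
    dneg <- (1 - a) / (1 - pc)
  }
  gr <- (g * dpos + (1 - g) * dneg) / n
  list(value = val, grad = array(gr, dim(p) %||% length(p)))
}

#' Ground-truth edge band
#'
#' Sobel gradient support of the binary mask, dilated by `dilate` pixels
#' (3x3 structuring element applied `dilate` times).
#'
#' @param g Binary matrix `H x W`.
#' @param dilate Dilation radius in pixels (default 1).
#' @return Logical matrix marking the edge band.
#' @export
edge_band <- function(g, dilate = 1L) {
  g <- as.matrix(g)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  # replicate-pad so constant masks (and roots touching the border) do not
  # produce spurious border edges
  sx <- conv2_same(g, kx, replicate = TRUE)
  sy <- conv2_same(g, t(kx), replicate = TRUE)
  e <- (abs(sx) + abs(sy)) > 0
  for (i in seq_len(dilate)) e <- dilate3x3(e)
  e
}

# 2-D correlation, output size = input size; zero or replicate padding.
conv2_same <- function(m, k, replicate = FALSE) {
  H <- nrow(m); W <- ncol(m)
  kh <- nrow(k); kw <- ncol(k)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  P <- matrix(0, H + 2L * ph, W + 2L * pw)
  P[ph + seq_len(H), pw + seq_len(W)] <- m
  if (replicate) {
    ri <- c(rep(1L, ph), seq_len(H), rep(H, ph))
    ci <- c(rep(1L, pw), seq_len(W), rep(W, pw))
    P <- m[ri, ci, drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    if (k[i, j] == 0) next
    out <- out + k[i, j] * P[(i - 1L) + seq_len(H), (j - 1L) + seq_len(W)]
  }
  out
}

dilate3x3 <- function(e) {
  H <- nrow(e); W <- ncol(e)
  P <- matrix(FALSE, H + 2L, W + 2L)
  P[1L + seq_len(H), 1L + seq_len(W)] <- e
  out <- matrix(FALSE, H, W)
  for (i in 0:2) for (j in 0:2)
    out <- out | P[i + seq_len(H), j + seq_len(W)]
  out
}

#' Edge loss
#'
#' Mean binary cross-entropy of `p` against `g`, restricted to the
#' ground-truth edge band (Sobel support dilated by `dilate` px).  Defined
#' as 0 when the band is empty (constant masks).
#'
#' @inheritParams dice_loss
#' @param dilate Edge-band dilation radius.
#' @return Scalar loss, or a list `(value, grad)`.
#' @export
edge_loss <- function(p, g, dilate = 1L, grad = FALSE) {
  check_pg(p, g)
  pm <- spatial_matrix(p)
  gm <- spatial_matrix(g)
  val <- 0
  gr <- array(0, dim(pm))
  E <- edge_band(gm, dilate)
  nE <- sum(E)
  if (nE > 0) {
    pc <- clamp(pm, PROB_EPS, 1 - PROB_EPS)
    bce <- -(gm * log(pc) + (1 - gm) * log(1 - pc))
    val <- sum(bce[E]) / nE
    d <- (-gm / pc + (1 - gm) / (1 - pc)) / nE
    gr[E] <- d[E]
  }
  if (!grad) return(val)
  list(value = val, grad = array(gr, dim(p) %||% length(p)))
}

# Accept (H, W), (1, H, W) or (1, H, W, 1) and return the H x W matrix.
spatial_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop_invalid("expected a spatial map, got a bare vector")
  if (length(d) == 2L) return(x)
  if (length(d) == 3L && d[1] == 1L) return(matrix(x, d[2], d[3]))
  if (length(d) == 4L && d[1] == 1L && d[4] == 1L) return(matrix(x, d[2], d[3]))
  stop_invalid("expected a single-channel spatial map")
}

#' Hybrid total loss
#'
#' `w_focal * L_focal + w_dice * L_dice + w_edge * L_edge` (+ optional plain
#' BCE), the training objective.
#'
#' @inheritParams dice_loss
#' @param weights A [loss_weights()] vector.
#' @param params A [focal_params()] vector.
#' @param smooth Dice smoothing.
#' @param dilate Edge-band dilation.
#' @return Scalar loss, or a list `(value, components, grad)`.
#' @export
total_loss <- function(p, g, weights = loss_weights(),
                       params = focal_params(), smooth = 1, dilate = 1L,
                       grad = FALSE) {
  f <- focal_loss(p, g, params, grad = grad)
  d <- dice_loss(p, g, smooth, grad = grad)
  e <- edge_loss_batch(p, g, dilate, grad = grad)
  b <- if (weights[["bce"]] > 0) bce_loss(p, g, grad = grad) else
    if (grad) list(value = 0, grad = 0) else 0
  if (!grad) {
    return(weights[["focal"]] * f + weights[["dice"]] * d +
             weights[["edge"]] * e + weights[["bce"]] * b)
  }
  val <- weights[["focal"]] * f$value + weights[["dice"]] * d$value +
    weights[["edge"]] * e$value + weights[["bce"]] * b$value
  gr <- weights[["focal"]] * f$grad + weights[["dice"]] * d$grad +
    weights[["edge"]] * e$grad + weights[["bce"]] * b$grad
  list(value = val,
       components = c(focal = unname(f$value %||% f),
                      dice = unname(d$value %||% d),
                      edge = unname(e$value %||% e)),
       grad = gr)
}

# Edge loss over a (1, H, W, N) batch: per-sample bands, averaged.
edge_loss_batch <- function(p, g, dilate = 1L, grad = FALSE) {
  d <- dim(p)
  if (!is.null(d) && length(d) == 4L && d[4] > 1L) {
    vals <- numeric(d[4])
    grs <- array(0, d)
    for (n in seq_len(d[4])) {
      r <- edge_loss(p[, , , n, drop = FALSE], g[, , , n, drop = FALSE],
                     dilate, grad = grad)
      if (grad) {
        vals[n] <- r$value
        grs[, , , n] <- r$grad / d[4]
      } else vals[n] <- r
    }
    if (grad) return(list(value = mean(vals), grad = grs))
    return(mean(vals))
  }
  edge_loss(p, g, dilate, grad = grad)
}

bce_loss <- function(p, g, grad = FALSE) {
  check_pg(p, g)
  pc <- clamp(p, PROB_EPS, 1 - PROB_EPS)
  val <- mean(-(g * log(pc) + (1 - g) * log(1 - pc)))
  if (!grad) return(val)
  list(value = val,
       grad = array((-g / pc + (1 - g) / (1 - pc)) / length(p),
                    dim(p) %||% length(p)))
}
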