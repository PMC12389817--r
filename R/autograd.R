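# Minimal reverse-mode autodiff over 4-D arrays laid out (C, H, W, N).
#
# No tensor framework is available in this environment, so the layers the
# network needs (convolution, batch norm, pooling, bilinear upsampling,
# pointwise ops, channel/spatial reductions) are implemented directly.
# A "node" is an environment holding value, grad, parent nodes and a
# backward closure; nodes are appended to a tape in creation order, which
# is a topological order, so backpropagation is a single reverse sweep.
#
# The channel-first (C, H, W, N) layout is chosen deliberately: R recycles
# a length-C vector over the first dimension of an array, which makes all
# per-channel broadcasts (batch norm, biases, channel attention) free, and
# a (C, H*W*N) reshape is a zero-copy dim<- assignment, which makes the
# per-offset matrix-product convolution fast.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_input <- function(tape, value) ad_node(tape, value)

# Reverse sweep.  `seed_grad` is dL/d(root$value), same shape as the value.
ad_backward <- function(tape, root, seed_grad) {
  root$grad <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    if (!identical(nd, root)) nd$grad <- NULL  # free memory as we go
  }
  invisible(NULL)
}

dim4 <- function(x) {
  d <- dim(x)
  if (length(d) != 4L) stop("expected a 4-d array")
  d
}

# Sum an array over dims 2 and 3, returning (C, 1, 1, N).
sum_hw <- function(v) {
  d <- dim4(v)
  m <- v
  dim(m) <- c(d[1], d[2] * d[3], d[4])
  out <- matrix(0, d[1], d[4])
  for (n in seq_len(d[4])) out[, n] <- rowSums(matrix(m[, , n], nrow = d[1]))
  array(out, c(d[1], 1L, 1L, d[4]))
}

# ---- convolution -----------------------------------------------------------

# x: (Cin, H, W, N); w: (k, k, Cin, Cout); b: length Cout.  Stride 1 with
# zero padding; im2col packing in src/conv.cpp, arithmetic through BLAS.
conv_wmat <- function(wv) {
  k <- dim(wv)[1]; C <- dim(wv)[3]; Cout <- dim(wv)[4]
  W2 <- aperm(wv, c(3, 1, 2, 4))
  dim(W2) <- c(C * k * k, Cout)
  W2
}

conv2d_forward <- function(xv, wv, bv, pad) {
  d <- dim4(xv)
  k <- dim(wv)[1]
  X <- cpp_im2col(xv, as.integer(k), as.integer(pad))
  out <- crossprod(conv_wmat(wv), X) + as.vector(bv)
  Ho <- d[2] + 2L * pad - k + 1L
  Wo <- d[3] + 2L * pad - k + 1L
  dim(out) <- c(dim(wv)[4], Ho, Wo, d[4])
  list(out = out, X = X, Ho = Ho, Wo = Wo)
}

ad_conv2d <- function(x, w, b, pad = 0L) {
  wv <- w$value
  k <- dim(wv)[1]
  d <- dim4(x$value)
  fw <- conv2d_forward(x$value, wv, b$value, pad)
  env <- new.env(parent = emptyenv())
  env$X <- fw$X
  ad_node(x$tape, fw$out, parents = list(x, w, b), backward = function(g) {
    Cout <- dim(wv)[4]
    gm <- g
    dim(gm) <- c(Cout, length(g) / Cout)
    dW2 <- tcrossprod(env$X, gm)                # (C*k*k, Cout)
    env$X <- NULL
    dim(dW2) <- c(dim(wv)[3], k, k, Cout)
    dcols <- conv_wmat(wv) %*% gm               # (C*k*k, M)
    list(cpp_col2im(dcols, dim(wv)[3], d[2], d[3], d[4],
                    as.integer(k), as.integer(pad)),
         aperm(dW2, c(2, 3, 1, 4)),
         rowSums(gm))
  })
}

# ---- batch normalization ---------------------------------------------------

# gamma/beta are length-C numeric parameter nodes.  `state` is an
# environment; `key` indexes the layer's running moments within it.
ad_batchnorm <- function(x, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  d <- dim4(xv)
  C <- d[1]; m <- d[2] * d[3] * d[4]
  xm <- xv
  dim(xm) <- c(C, m)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu * mu
    va <- pmax(va, 0)
    st <- state[[key]]
    state[[key]] <- list(mean = (1 - momentum) * st$mean + momentum * mu,
                         var  = (1 - momentum) * st$var + momentum * va)
  } else {
    st <- state[[key]]
    mu <- st$mean
    va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- (xv - mu) * inv            # length-C recycling over dim 1
  out <- gamma$value * xhat + beta$value
  ad_node(x$tape, out, parents = list(x, gamma, beta), backward = function(g) {
    gm <- g; dim(gm) <- c(C, m)
    xh <- xhat; dim(xh) <- c(C, m)
    dgamma <- rowSums(gm * xh)
    dbeta <- rowSums(gm)
    dxhat <- g * gamma$value
    if (training) {
      dxh <- dxhat; dim(dxh) <- c(C, m)
      s1 <- rowSums(dxh)
      s2 <- rowSums(dxh * xh)
      dx <- (dxhat - (s1 / m) - xhat * (s2 / m)) * inv
    } else {
      dx <- dxhat * inv
    }
    list(dx, dgamma, dbeta)
  })
}

# ---- pointwise ops ---------------------------------------------------------

ad_relu <- function(x) {
  out <- pmax(x$value, 0)
  mask <- x$value > 0
  ad_node(x$tape, out, parents = list(x),
          backward = function(g) list(g * mask))
}

ad_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$value))
  ad_node(x$tape, s, parents = list(x),
          backward = function(g) list(g * s * (1 - s)))
}

ad_add <- function(x, y) {
  ad_node(x$tape, x$value + y$value, parents = list(x, y),
          backward = function(g) list(g, g))
}

ad_mul <- function(x, y) {
  ad_node(x$tape, x$value * y$value, parents = list(x, y),
          backward = function(g) list(g * y$value, g * x$value))
}

# Multiply x (C,H,W,N) by channel weights s (C,1,1,N).
ad_scale_channels <- function(x, s) {
  d <- dim4(x$value)
  sb <- s$value[, rep(1L, d[2]), rep(1L, d[3]), , drop = FALSE]
  ad_node(x$tape, x$value * sb, parents = list(x, s), backward = function(g) {
    list(g * sb, sum_hw(g * x$value))
  })
}

# Multiply x (C,H,W,N) by a spatial map m (1,H,W,N).
ad_scale_spatial <- function(x, m) {
  d <- dim4(x$value)
  mb <- m$value[rep(1L, d[1]), , , , drop = FALSE]
  ad_node(x$tape, x$value * mb, parents = list(x, m), backward = function(g) {
    v <- g * x$value
    dim(v) <- c(d[1], d[2] * d[3] * d[4])
    dm <- colSums(v)
    dim(dm) <- c(1L, d[2], d[3], d[4])
    list(g * mb, dm)
  })
}

ad_concat_channels <- function(x, y) {
  dx <- dim4(x$value); dy <- dim4(y$value)
  out <- array(0, c(dx[1] + dy[1], dx[2], dx[3], dx[4]))
  out[seq_len(dx[1]), , , ] <- x$value
  out[dx[1] + seq_len(dy[1]), , , ] <- y$value
  ad_node(x$tape, out, parents = list(x, y), backward = function(g) {
    list(g[seq_len(dx[1]), , , , drop = FALSE],
         g[dx[1] + seq_len(dy[1]), , , , drop = FALSE])
  })
}

# ---- pooling ---------------------------------------------------------------

ad_maxpool2 <- function(x) {
  d <- dim4(x$value)
  if (d[2] %% 2L || d[3] %% 2L)
    stop_invalid("maxpool2 needs even spatial dims, got ", d[2], "x", d[3])
  ri <- seq(1L, d[2], by = 2L); ci <- seq(1L, d[3], by = 2L)
  s <- list(x$value[, ri, ci, , drop = FALSE],
            x$value[, ri + 1L, ci, , drop = FALSE],
            x$value[, ri, ci + 1L, , drop = FALSE],
            x$value[, ri + 1L, ci + 1L, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    dx <- array(0, d)
    taken <- array(FALSE, dim(out))
    put <- function(slice, rows, cols) {
      m <- (slice == out) & !taken
      taken <<- taken | m
      dx[, rows, cols, ] <<- dx[, rows, cols, , drop = FALSE] + g * m
    }
    put(s[[1]], ri, ci); put(s[[2]], ri + 1L, ci)
    put(s[[3]], ri, ci + 1L); put(s[[4]], ri + 1L, ci + 1L)
    list(dx)
  })
}

# Global average / max pool over (H, W) -> (C, 1, 1, N).
ad_global_avgpool <- function(x) {
  d <- dim4(x$value)
  hw <- d[2] * d[3]
  out <- sum_hw(x$value) / hw
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    gb <- g[, rep(1L, d[2]), rep(1L, d[3]), , drop = FALSE]
    list(gb / hw)
  })
}

ad_global_maxpool <- function(x) {
  d <- dim4(x$value)
  C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
  m <- x$value
  dim(m) <- c(C, hw, N)
  out <- array(0, c(C, 1L, 1L, N))
  amax <- matrix(0L, C, N)
  for (n in seq_len(N)) {
    mm <- matrix(m[, , n], nrow = C)
    j <- max.col(mm, ties.method = "first")
    amax[, n] <- j
    out[, 1L, 1L, n] <- mm[cbind(seq_len(C), j)]
  }
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    dx <- numeric(C * hw * N)
    for (n in seq_len(N)) {
      lin <- seq_len(C) + (amax[, n] - 1L) * C + (n - 1L) * C * hw
      dx[lin] <- dx[lin] + g[, 1L, 1L, n]
    }
    dim(dx) <- d
    list(dx)
  })
}

# Channel-wise mean / max over C -> (1, H, W, N).
ad_channel_mean <- function(x) {
  d <- dim4(x$value)
  C <- d[1]
  m <- x$value
  dim(m) <- c(C, d[2] * d[3] * d[4])
  out <- colMeans(m)
  dim(out) <- c(1L, d[2], d[3], d[4])
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    list(g[rep(1L, C), , , , drop = FALSE] / C)
  })
}

ad_channel_max <- function(x) {
  d <- dim4(x$value)
  C <- d[1]; M <- d[2] * d[3] * d[4]
  m <- x$value
  dim(m) <- c(C, M)
  j <- max.col(t(m), ties.method = "first")
  out <- m[cbind(j, seq_len(M))]
  dim(out) <- c(1L, d[2], d[3], d[4])
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    dx <- numeric(C * M)
    dx[j + (seq_len(M) - 1L) * C] <- g
    dim(dx) <- d
    list(dx)
  })
}

# ---- bilinear upsampling ---------------------------------------------------

#' Interpolation matrix for 1-D bilinear resampling (half-pixel centers,
#' i.e. the align_corners = FALSE convention).
#' @noRd
bilinear_map <- function(n_out, n_in) {
  M <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5        # 0-based source coordinate
    lo <- floor(src)
    w <- src - lo
    lo <- min(max(lo, 0), n_in - 1)
    hi <- min(lo + 1, n_in - 1)
    if (src < 0) w <- 0
    if (src > n_in - 1) { w <- 0; lo <- n_in - 1; hi <- n_in - 1 }
    M[i, lo + 1] <- M[i, lo + 1] + (1 - w)
    M[i, hi + 1] <- M[i, hi + 1] + w
  }
  M
}

# Apply matrix M (n_out x dim(a)[d]) along dimension d of a 4-D array.
apply_along <- function(a, d, M) {
  perm <- c(d, setdiff(1:4, d))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  dim(ap) <- c(dp[1], prod(dp[-1]))
  out <- M %*% ap
  dim(out) <- c(nrow(M), dp[-1])
  aperm(out, order(perm))
}

ad_upsample2 <- function(x) {
  d <- dim4(x$value)
  Mh <- bilinear_map(2L * d[2], d[2])
  Mw <- bilinear_map(2L * d[3], d[3])
  out <- apply_along(apply_along(x$value, 2L, Mh), 3L, Mw)
  ad_node(x$tape, out, parents = list(x), backward = function(g) {
    list(apply_along(apply_along(g, 3L, t(Mw)), 2L, t(Mh)))
  })
}
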