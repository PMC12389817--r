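# The improved U-Net: DoubleConv encoder with channel-spatial attention,
# 1024-channel bottleneck, and a decoder whose skip fusion is either plain
# concatenation (original U-Net) or UpAdd -- element-wise addition of the
# aligned skip and upsampled features, modulated by attention computed on
# their concatenation.  All six ablation variants ({none, se, cbam} x
# {concat, upadd}) are reachable through the configuration.

#' Model configuration
#'
#' @param in_channels Input channels (3 for HSV/RGB).
#' @param stage_channels Encoder stage widths, strictly doubling
#'   (default `c(64, 128, 256, 512)`).
#' @param bottleneck_channels Bottleneck width; must be twice the last
#'   stage (default 1024).
#' @param attention `"cbam"`, `"se"` or `"none"`.
#' @param fusion `"upadd"` or `"concat"`.
#' @param reduction_ratio Bottleneck ratio of the attention MLPs (default
#'   16); must divide every attended channel count.
#' @param out_channels Output channels (1: root probability).
#' @return List of class `unet_config`.
#' @export
unet_config <- function(in_channels = 3L,
                        stage_channels = c(64L, 128L, 256L, 512L),
                        bottleneck_channels = 2L * stage_channels[length(stage_channels)],
                        attention = c("cbam", "se", "none"),
                        fusion = c("upadd", "concat"),
                        reduction_ratio = 16L,
                        out_channels = 1L) {
  attention <- match.arg(attention)
  fusion <- match.arg(fusion)
  sc <- as.integer(stage_channels)
  if (length(sc) < 2L || any(sc[-1] != 2L * sc[-length(sc)]))
    stop_config("stage_channels must strictly double")
  if (bottleneck_channels != 2L * sc[length(sc)])
    stop_config("bottleneck must be twice the last stage")
  r <- as.integer(reduction_ratio)
  if (attention != "none") {
    attended <- c(sc, bottleneck_channels)
    if (fusion == "upadd") attended <- c(attended, 2L * sc)
    bad <- attended[attended < r | attended %% r != 0L]
    if (length(bad))
      stop_config("reduction_ratio ", r, " incompatible with channel counts ",
                  paste(unique(bad), collapse = ", "))
  }
  structure(list(in_channels = as.integer(in_channels), stage_channels = sc,
                 bottleneck_channels = as.integer(bottleneck_channels),
                 attention = attention, fusion = fusion,
                 reduction_ratio = r, out_channels = as.integer(out_channels)),
            class = "unet_config")
}

he_init <- function(dims, fan_in) array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

add_conv <- function(P, name, k, cin, cout) {
  P[[paste0(name, ".w")]] <- he_init(c(k, k, cin, cout), k * k * cin)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

add_bn <- function(P, name, C) {
  P[[paste0(name, ".g")]] <- rep(1, C)
  P[[paste0(name, ".b")]] <- numeric(C)
  P
}

add_attention <- function(P, name, C, cfg) {
  if (cfg$attention == "none") return(P)
  r <- cfg$reduction_ratio
  P <- add_conv(P, paste0(name, ".mlp1"), 1L, C, C %/% r)
  P <- add_conv(P, paste0(name, ".mlp2"), 1L, C %/% r, C)
  if (cfg$attention == "cbam") P <- add_conv(P, paste0(name, ".sp"), 7L, 2L, 1L)
  P
}

add_double_conv <- function(P, name, cin, cout, cfg, attended = TRUE) {
  P <- add_conv(P, paste0(name, ".c1"), 3L, cin, cout)
  P <- add_bn(P, paste0(name, ".bn1"), cout)
  P <- add_conv(P, paste0(name, ".c2"), 3L, cout, cout)
  P <- add_bn(P, paste0(name, ".bn2"), cout)
  if (attended) P <- add_attention(P, paste0(name, ".att"), cout, cfg)
  P
}

#' Initialize an improved U-Net
#'
#' He-initialized convolution weights, unit batch-norm scales, zero biases.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the random initialization.
#' @return A model object: list with `config`, `params` (named list of
#'   arrays), `bn` (running batch-norm moments), `seed`.
#' @export
unet_init <- function(config = unet_config(), seed = 0L) {
  with_seed(seed, {
    sc <- config$stage_channels
    L <- length(sc)
    P <- list()
    cin <- config$in_channels
    for (l in seq_len(L)) {
      P <- add_double_conv(P, paste0("enc", l), cin, sc[l], config)
      cin <- sc[l]
    }
    P <- add_double_conv(P, "bott", sc[L], config$bottleneck_channels, config)
    deep <- config$bottleneck_channels
    for (l in rev(seq_len(L))) {
      C <- sc[l]
      P <- add_conv(P, paste0("dec", l, ".align"), 1L, deep, C)
      if (config$fusion == "upadd" && config$attention != "none") {
        P <- add_attention(P, paste0("dec", l, ".fuse"), 2L * C, config)
        P <- add_conv(P, paste0("dec", l, ".red"), 1L, 2L * C, C)
        dc_in <- C
      } else if (config$fusion == "upadd") {
        dc_in <- C
      } else {
        dc_in <- 2L * C
      }
      P <- add_double_conv(P, paste0("dec", l, ".dc"), dc_in, C, config)
      deep <- C
    }
    P <- add_conv(P, "head", 1L, sc[1], config$out_channels)
    bn <- new.env(parent = emptyenv())
    for (nm in names(P)) {
      if (grepl("\\.bn[12]\\.g$", nm)) {
        key <- sub("\\.g$", "", nm)
        bn[[key]] <- list(mean = numeric(length(P[[nm]])),
                          var = rep(1, length(P[[nm]])))
      }
    }
    list(config = config, params = P, bn = bn, seed = as.integer(seed))
  })
}

# ---- forward graph ---------------------------------------------------------

fw_attention <- function(x, name, pn, cfg) {
  if (cfg$attention == "none") return(x)
  mlp <- function(v) {
    h <- ad_relu(ad_conv2d(v, pn[[paste0(name, ".mlp1.w")]],
                           pn[[paste0(name, ".mlp1.b")]], 0L))
    ad_conv2d(h, pn[[paste0(name, ".mlp2.w")]], pn[[paste0(name, ".mlp2.b")]], 0L)
  }
  if (cfg$attention == "se") {
    s <- ad_sigmoid(mlp(ad_global_avgpool(x)))
    return(ad_scale_channels(x, s))
  }
  mc <- ad_sigmoid(ad_add(mlp(ad_global_avgpool(x)), mlp(ad_global_maxpool(x))))
  f1 <- ad_scale_channels(x, mc)
  sp_in <- ad_concat_channels(ad_channel_mean(f1), ad_channel_max(f1))
  ms <- ad_sigmoid(ad_conv2d(sp_in, pn[[paste0(name, ".sp.w")]],
                             pn[[paste0(name, ".sp.b")]], 3L))
  ad_scale_spatial(f1, ms)
}

# Channel weights only, used by the UpAdd fusion (se: SE vector; cbam: Mc).
fw_channel_weights <- function(x, name, pn, cfg) {
  mlp <- function(v) {
    h <- ad_relu(ad_conv2d(v, pn[[paste0(name, ".mlp1.w")]],
                           pn[[paste0(name, ".mlp1.b")]], 0L))
    ad_conv2d(h, pn[[paste0(name, ".mlp2.w")]], pn[[paste0(name, ".mlp2.b")]], 0L)
  }
  if (cfg$attention == "se") {
    ad_sigmoid(mlp(ad_global_avgpool(x)))
  } else {
    ad_sigmoid(ad_add(mlp(ad_global_avgpool(x)), mlp(ad_global_maxpool(x))))
  }
}

fw_double_conv <- function(x, name, pn, bn, cfg, training, attended = TRUE) {
  h <- ad_conv2d(x, pn[[paste0(name, ".c1.w")]], pn[[paste0(name, ".c1.b")]], 1L)
  h <- ad_relu(ad_batchnorm(h, pn[[paste0(name, ".bn1.g")]],
                            pn[[paste0(name, ".bn1.b")]], bn,
                            paste0(name, ".bn1"), training))
  h <- ad_conv2d(h, pn[[paste0(name, ".c2.w")]], pn[[paste0(name, ".c2.b")]], 1L)
  h <- ad_relu(ad_batchnorm(h, pn[[paste0(name, ".bn2.g")]],
                            pn[[paste0(name, ".bn2.b")]], bn,
                            paste0(name, ".bn2"), training))
  if (attended) h <- fw_attention(h, paste0(name, ".att"), pn, cfg)
  h
}

#' Run the improved U-Net forward
#'
#' @param model A model from [unet_init()].
#' @param x Input array `(3, H, W)` or `(3, H, W, N)`; `H` and `W` must be
#'   divisible by 16 (four 2x2 poolings).  Values expected in `[0, 1]`.
#' @param training Logical; `TRUE` uses batch statistics and updates running
#'   moments, `FALSE` (inference) uses running statistics and is
#'   deterministic.
#' @param with_tape Internal: return the autodiff tape and parameter nodes
#'   for backpropagation instead of a plain array.
#' @return Probability array `(1, H, W, N)` in `[0, 1]` (sigmoid head), or a
#'   list `(tape, out, pnodes)` when `with_tape = TRUE`.
#' @export
unet_forward <- function(model, x, training = FALSE, with_tape = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  d <- dim4(x)
  cfg <- model$config
  if (d[1] != cfg$in_channels)
    stop_invalid("expected ", cfg$in_channels, " input channels, got ", d[1])
  if (d[2] %% 16L != 0L || d[3] %% 16L != 0L)
    stop_invalid("input H and W must be divisible by 16, got ",
                 d[2], "x", d[3], "; resize or pad the input explicitly")
  tape <- ad_tape()
  pn <- lapply(model$params, function(v) ad_input(tape, v))
  xin <- ad_input(tape, x)
  sc <- cfg$stage_channels
  L <- length(sc)
  skips <- vector("list", L)
  h <- xin
  for (l in seq_len(L)) {
    h <- fw_double_conv(h, paste0("enc", l), pn, model$bn, cfg, training)
    skips[[l]] <- h
    h <- ad_maxpool2(h)
  }
  h <- fw_double_conv(h, "bott", pn, model$bn, cfg, training)
  for (l in rev(seq_len(L))) {
    up <- ad_upsample2(h)
    E <- ad_conv2d(up, pn[[paste0("dec", l, ".align.w")]],
                   pn[[paste0("dec", l, ".align.b")]], 0L)
    S <- skips[[l]]
    if (cfg$fusion == "concat") {
      merged <- ad_concat_channels(S, E)
    } else {
      merged <- ad_add(S, E)
      if (cfg$attention != "none") {
        cat2 <- ad_concat_channels(S, E)
        wc2 <- fw_channel_weights(cat2, paste0("dec", l, ".fuse"), pn, cfg)
        wc <- ad_sigmoid(ad_conv2d(wc2, pn[[paste0("dec", l, ".red.w")]],
                                   pn[[paste0("dec", l, ".red.b")]], 0L))
        merged <- ad_scale_channels(merged, wc)
        if (cfg$attention == "cbam") {
          f1 <- ad_scale_channels(cat2, wc2)
          sp_in <- ad_concat_channels(ad_channel_mean(f1), ad_channel_max(f1))
          ms <- ad_sigmoid(ad_conv2d(sp_in,
                                     pn[[paste0("dec", l, ".fuse.sp.w")]],
                                     pn[[paste0("dec", l, ".fuse.sp.b")]], 3L))
          merged <- ad_scale_spatial(merged, ms)
        }
      }
    }
    h <- fw_double_conv(merged, paste0("dec", l, ".dc"), pn, model$bn, cfg,
                        training)
  }
  out <- ad_sigmoid(ad_conv2d(h, pn[["head.w"]], pn[["head.b"]], 0L))
  if (with_tape) list(tape = tape, out = out, pnodes = pn) else out$value
}

#' Predict root-probability maps for a batch of inputs
#'
#' Inference-mode forward pass (running batch-norm statistics), optionally
#' binarized.
#'
#' @param model A trained model.
#' @param inputs List of `(3, H, W)` arrays, or one `(3, H, W, N)` array.
#' @param threshold Optional binarization cutoff; `NULL` returns
#'   probabilities.
#' @param batch_size Samples per forward pass.
#' @return List of `(1, H, W)` arrays.
#' @export
unet_predict <- function(model, inputs, threshold = NULL, batch_size = 8L) {
  if (is.array(inputs)) {
    inputs <- if (length(dim(inputs)) == 3L) list(inputs) else
      lapply(seq_len(dim(inputs)[4]), function(n) inputs[, , , n])
  }
  out <- vector("list", length(inputs))
  i <- 1L
  while (i <= length(inputs)) {
    j <- min(i + batch_size - 1L, length(inputs))
    d <- dim(inputs[[i]])
    xb <- array(0, c(d, j - i + 1L))
    for (k in i:j) xb[, , , k - i + 1L] <- inputs[[k]]
    pb <- unet_forward(model, xb, training = FALSE)
    for (k in i:j) {
      p <- pb[, , , k - i + 1L, drop = FALSE]
      dim(p) <- c(1L, d[2], d[3])
      if (!is.null(threshold)) p <- (p >= threshold) * 1
      out[[k]] <- p
    }
    i <- j + 1L
  }
  out
}

# ---- stand-alone attention operators (plain arrays, single sample) --------
# These mirror the network's internal blocks and serve as directly
# checkable implementations of the attention equations.

#' Channel attention weights
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with global per-channel
#' pooling and a shared two-layer bottleneck MLP `C -> C/r -> C` (ReLU in
#' between).
#'
#' @param f Feature map `(C, H, W)`.
#' @param w1 `C x Ch` weight matrix of the squeeze layer; `b1` its bias.
#' @param w2 `Ch x C` weight matrix of the excite layer; `b2` its bias.
#' @param b1,b2 Bias vectors.
#' @return Numeric vector of `C` weights, each in (0, 1).
#' @export
channel_attention <- function(f, w1, b1, w2, b2) {
  C <- dim(f)[1]
  if (nrow(w1) != C)
    stop_config("w1 must have ", C, " rows to match the channel count")
  m <- f
  dim(m) <- c(C, prod(dim(f)[2:3]))
  mlp <- function(v) {
    h <- pmax(drop(crossprod(w1, v)) + b1, 0)
    drop(crossprod(w2, h)) + b2
  }
  a <- mlp(rowMeans(m))
  b <- mlp(apply(m, 1, max))
  1 / (1 + exp(-(a + b)))
}

#' Spatial attention map
#'
#' `Ms = sigmoid(conv7x7([mean_c(F'); max_c(F')]))`: channel-wise average and
#' max maps are stacked and convolved with a `k x k` kernel (padding
#' `(k-1)/2` preserves size).
#'
#' @param fprime Feature map `(C, H, W)`.
#' @param kernel Convolution kernel `(k, k, 2, 1)`.
#' @param bias Scalar bias.
#' @return Array `(1, H, W)` of weights in (0, 1).
#' @export
spatial_attention <- function(fprime, kernel, bias = 0) {
  d <- dim(fprime)
  m <- fprime
  dim(m) <- c(d[1], d[2] * d[3])
  stacked <- array(0, c(2L, d[2], d[3], 1L))
  stacked[1, , , 1] <- colMeans(m)
  stacked[2, , , 1] <- if (d[1] == 1L) m else do.call(pmax, asplit(m, 1))
  k <- dim(kernel)[1]
  z <- conv2d_forward(stacked, kernel, bias, (k - 1L) %/% 2L)$out
  out <- 1 / (1 + exp(-z))
  dim(out) <- c(1L, d[2], d[3])
  out
}

#' Refine a feature map with CBAM
#'
#' Sequential channel-then-spatial attention:
#' `F' = Mc(F) * F`, `out = Ms(F') * F'`.  Output magnitude is bounded by
#' the input element-wise since both gates lie in (0, 1).
#'
#' @param f Feature map `(C, H, W)`.
#' @param mlp List with `w1`, `b1`, `w2`, `b2` (see [channel_attention()]).
#' @param kernel,bias Spatial kernel `(k, k, 2, 1)` and its bias.
#' @return List with `out` `(C, H, W)`, `channel` (length-C weights) and
#'   `spatial` (`(1, H, W)` map).
#' @export
cbam_refine <- function(f, mlp, kernel, bias = 0) {
  mc <- channel_attention(f, mlp$w1, mlp$b1, mlp$w2, mlp$b2)
  fp <- f * mc                       # length-C recycling over dim 1
  ms <- spatial_attention(fp, kernel, bias)
  out <- fp * ms[rep(1L, dim(f)[1]), , , drop = FALSE]
  list(out = out, channel = mc, spatial = ms)
}
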