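# Model-input preparation and the four stochastic augmentations.
#
# Images go to the network as channel-first HSV arrays in [0, 1]; masks stay
# strictly binary through every augmentation path (nearest-neighbour
# resampling + re-thresholding at 0.5).

#' Augmentation configuration
#'
#' Each of the four augmentations (color jitter, random crop + resize,
#' random rotation, random flip) fires independently with probability
#' `prob`.
#'
#' @param prob Per-augmentation application probability (default 0.3).
#' @param jitter_limit Brightness/contrast/saturation factors are drawn
#'   uniformly in `[1 - jitter_limit, 1 + jitter_limit]` (default 0.5,
#'   i.e. up to +/- 50 percent).
#' @param crop_scale Area-fraction interval for the random square crop
#'   (default `c(0.2, 1)`).
#' @param rot_limit Rotation angle drawn uniformly in
#'   `[-rot_limit, rot_limit]` degrees (default 90).
#' @param target_size Output side length in pixels (default 256).
#' @return List of class `augment_config`.
#' @export
augment_config <- function(prob = 0.3, jitter_limit = 0.5,
                           crop_scale = c(0.2, 1), rot_limit = 90,
                           target_size = 256L) {
  if (prob < 0 || prob > 1) stop_config("prob must be in [0, 1]")
  if (crop_scale[1] <= 0 || crop_scale[2] > 1 || crop_scale[1] > crop_scale[2])
    stop_config("crop_scale must be within (0, 1]")
  structure(list(prob = prob, jitter_limit = jitter_limit,
                 crop_scale = crop_scale, rot_limit = rot_limit,
                 target_size = as.integer(target_size)),
            class = "augment_config")
}

#' Convert an RGB image to a normalized channel-first model input
#'
#' Resizes to `size x size`, converts RGB to HSV (better root/soil contrast),
#' and reorders to `(C, H, W)` with all values in `[0, 1]`.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param size Target side in pixels (default 256).
#' @param colorspace `"hsv"` (default) or `"rgb"`.
#' @return Numeric array `3 x size x size`.
#' @export
to_model_input <- function(image, size = 256L, colorspace = c("hsv", "rgb")) {
  colorspace <- match.arg(colorspace)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_invalid("expected an H x W x 3 RGB array")
  img <- resize_image(image, size, size, "bilinear")
  img <- clamp(img, 0, 1)
  if (colorspace == "hsv") img <- rgb_to_hsv_array(img)
  aperm(img, c(3, 1, 2))
}

# Rotate an H x W (x C) array by `angle` degrees about the image center.
# Inverse mapping with either bilinear or nearest sampling; pixels mapped
# from outside the source are filled with 0 (black, consistent with patch
# padding).
rotate_image <- function(img, angle, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  gray <- length(dim(img)) < 3L
  if (gray) dim(img) <- c(dim(img), 1L)
  d <- dim(img)
  th <- angle * pi / 180
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  xx <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  # rotate output coords back into the source frame
  sy <- cy + yy * cos(th) - xx * sin(th)
  sx <- cx + yy * sin(th) + xx * cos(th)
  out <- array(0, d)
  if (method == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    lin <- (ci - 1) * d[1] + ri
    for (c in seq_len(d[3])) {
      ch <- matrix(0, d[1], d[2])
      src <- img[, , c]
      ch[ok] <- src[lin[ok]]
      out[, , c] <- ch
    }
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    for (c in seq_len(d[3])) {
      src <- img[, , c]
      acc <- matrix(0, d[1], d[2])
      for (dy in 0:1) for (dx in 0:1) {
        ri <- y0 + dy; ci <- x0 + dx
        w <- (if (dy) wy else 1 - wy) * (if (dx) wx else 1 - wx)
        ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2] & w > 0
        lin <- (ci - 1) * d[1] + ri
        add <- matrix(0, d[1], d[2])
        add[ok] <- src[lin[ok]] * w[ok]
        acc <- acc + add
      }
      out[, , c] <- acc
    }
  }
  if (gray) dim(out) <- dim(out)[1:2]
  out
}

jitter_color <- function(img, limit) {
  fb <- runif(1, 1 - limit, 1 + limit)   # brightness
  fc <- runif(1, 1 - limit, 1 + limit)   # contrast
  fs <- runif(1, 1 - limit, 1 + limit)   # saturation
  img <- img * fb
  m <- mean(img)
  img <- (img - m) * fc + m
  gray <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  for (c in 1:3) img[, , c] <- gray + (img[, , c] - gray) * fs
  clamp(img, 0, 1)
}

#' Apply the four stochastic augmentations to an image/mask pair
#'
#' Color jitter, random square crop + resize, random rotation, and random
#' flip each fire independently with probability `config$prob`.  Geometric
#' transforms are applied identically to image and mask (mask with
#' nearest-neighbour sampling, re-thresholded at 0.5); color jitter touches
#' the image only.  The pair is finally resized to
#' `config$target_size`.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param mask `H x W` binary matrix.
#' @param config An [augment_config()].
#' @param seed Optional integer seed for a reproducible draw.
#' @return List with elements `image` and `mask` (both
#'   `target_size`-sized), and `applied`, a named logical vector.
#' @export
augment_pair <- function(image, mask, config = augment_config(), seed = NULL) {
  if (!all(dim(image)[1:2] == dim(mask)[1:2]))
    stop_invalid("image and mask sizes differ")
  run <- function() {
    applied <- stats::runif(4) < config$prob
    names(applied) <- c("jitter", "crop", "rotate", "flip")
    if (applied["jitter"]) image <- jitter_color(image, config$jitter_limit)
    if (applied["crop"]) {
      H <- dim(image)[1]; W <- dim(image)[2]
      for (try in 1:20) {
        frac <- runif(1, config$crop_scale[1], config$crop_scale[2])
        side <- max(1L, round(sqrt(frac) * min(H, W)))
        if (side <= H && side <= W) break
      }
      r0 <- sample.int(H - side + 1L, 1L) - 1L
      c0 <- sample.int(W - side + 1L, 1L) - 1L
      image <- image[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
      mask <- mask[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
    }
    if (applied["rotate"]) {
      ang <- runif(1, -config$rot_limit, config$rot_limit)
      image <- rotate_image(image, ang, "bilinear")
      mask <- rotate_image(mask, ang, "nearest")
    }
    if (applied["flip"]) {
      if (runif(1) < 0.5) {          # horizontal (mirror columns)
        image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
        mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
      } else {                       # vertical
        image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
        mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
      }
    }
    ts <- config$target_size
    if (!all(dim(image)[1:2] == c(ts, ts))) {
      image <- resize_image(image, ts, ts, "bilinear")
      mask <- resize_image(mask, ts, ts, "nearest")
    }
    list(image = clamp(image, 0, 1), mask = (mask > 0.5) * 1,
         applied = applied)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
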