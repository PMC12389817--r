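# Patch bookkeeping: mask binarization, sliding-window tiling with black
# edge padding, and the 7:2:1 random split.

#' Binarize a ground-truth mask
#'
#' Grayscale annotation rasters (white root on black soil) are normalized to
#' `[0, 1]` and thresholded; anti-aliased gray edges therefore never survive
#' into training targets.  A leading channel dimension is prepended so the
#' result is ready to use as a model target.
#'
#' @param mask Numeric matrix. Values may be on the 8-bit `[0, 255]` scale or
#'   already in `[0, 1]`; RGB arrays are first collapsed to luminance.
#' @param threshold Threshold on the normalized `[0, 1]` scale (default 0.5).
#' @return Numeric array `1 x H x W` with values in `{0, 1}`.
#' @export
binarize_mask <- function(mask, threshold = 0.5) {
  if (length(mask) == 0L) stop_invalid("empty mask raster")
  if (length(dim(mask)) == 3L) {          # RGB -> luminance
    mask <- 0.299 * mask[, , 1] + 0.587 * mask[, , 2] + 0.114 * mask[, , 3]
  }
  if (is.null(dim(mask))) stop_invalid("mask must be a matrix")
  if (any(mask < 0 | mask > 255)) stop_invalid("mask values outside [0, 255]")
  if (max(mask) > 1) mask <- mask / 255
  out <- array(0, c(1L, nrow(mask), ncol(mask)))
  out[1, , ] <- (mask > threshold) * 1
  out
}

#' Extract sliding-window patches from an image/mask pair
#'
#' Windows start at offsets 0, `stride`, 2`stride`, ... along each axis until
#' the image is covered; windows that extend past the border are filled with
#' `pad_value` so every patch is exactly `patch x patch`.  The patch count
#' per axis is `ceil(max(dim - patch, 0) / stride) + 1`.
#'
#' @param image `H x W x 3` (or `H x W`) numeric array.
#' @param mask Optional `H x W` numeric matrix aligned with `image`.
#' @param patch Window side in pixels.
#' @param stride Step between window origins; `patch >= stride > 0`.
#' @param pad_value Fill intensity for out-of-bounds regions (default 0,
#'   black).
#' @param source_id Identifier recorded in each patch's origin.
#' @return A `patch_set`: list with `patches` (each a list with `image`,
#'   `mask`, `source_id`, `row`, `col`; offsets are 0-based) and the tiling
#'   parameters.
#' @export
extract_patches <- function(image, mask = NULL, patch = 512L, stride = 256L,
                            pad_value = 0, source_id = "img") {
  if (stride <= 0L || patch < stride)
    stop_invalid("need patch >= stride > 0")
  d <- dim(image)
  if (is.null(d) || d[1] < 1L || d[2] < 1L)
    stop_invalid("image smaller than 1x1")
  H <- d[1]; W <- d[2]
  gray <- length(d) < 3L
  if (gray) dim(image) <- c(H, W, 1L)
  if (!is.null(mask) && !all(dim(mask)[1:2] == c(H, W)))
    stop_invalid("image and mask sizes differ")
  n_r <- ceiling(max(H - patch, 0) / stride) + 1L
  n_c <- ceiling(max(W - patch, 0) / stride) + 1L
  patches <- vector("list", n_r * n_c)
  k <- 0L
  for (r0 in (seq_len(n_r) - 1L) * stride) {
    for (c0 in (seq_len(n_c) - 1L) * stride) {
      pim <- array(pad_value, c(patch, patch, dim(image)[3]))
      rr <- seq(r0 + 1L, min(r0 + patch, H))
      cc <- seq(c0 + 1L, min(c0 + patch, W))
      pim[seq_along(rr), seq_along(cc), ] <- image[rr, cc, , drop = FALSE]
      if (gray) dim(pim) <- c(patch, patch)
      pm <- NULL
      if (!is.null(mask)) {
        pm <- matrix(pad_value, patch, patch)
        pm[seq_along(rr), seq_along(cc)] <- mask[rr, cc]
      }
      k <- k + 1L
      patches[[k]] <- list(image = pim, mask = pm, source_id = source_id,
                           row = r0, col = c0)
    }
  }
  structure(list(patches = patches, patch = patch, stride = stride,
                 source_dim = c(H, W)),
            class = "patch_set")
}

#' @export
length.patch_set <- function(x) length(x$patches)

#' Reassemble a source image from its patches
#'
#' Places every patch at its recorded origin (later patches overwrite
#' overlaps).  Used to verify that tiling is lossless up to padding.
#'
#' @param ps A `patch_set` from [extract_patches()].
#' @return Array of the padded source size.
#' @export
reconstruct_from_patches <- function(ps) {
  P <- ps$patch; s <- ps$stride
  H <- ps$source_dim[1]; W <- ps$source_dim[2]
  n_r <- ceiling(max(H - P, 0) / s) + 1L
  n_c <- ceiling(max(W - P, 0) / s) + 1L
  Hp <- (n_r - 1L) * s + P
  Wp <- (n_c - 1L) * s + P
  d3 <- if (length(dim(ps$patches[[1]]$image)) == 3L)
    dim(ps$patches[[1]]$image)[3] else 1L
  out <- array(0, c(Hp, Wp, d3))
  for (p in ps$patches) {
    im <- p$image
    if (length(dim(im)) < 3L) dim(im) <- c(dim(im), 1L)
    out[p$row + seq_len(P), p$col + seq_len(P), ] <- im
  }
  if (d3 == 1L) dim(out) <- c(Hp, Wp)
  out
}

#' Randomly split items into train/validation/test subsets
#'
#' Shuffles with the given seed, then assigns `floor(r1 * n)` items to
#' train, `floor(r2 * n)` to validation, and the remainder to test -- the
#' rule that reproduces a 1377/393/198 split of 1968 patches at 7:2:1.
#'
#' @param items A list (e.g. `patch_set$patches`) or a vector of ids.
#' @param ratios Length-3 non-negative numeric summing to 1.
#' @param seed Integer RNG seed; same seed, same split.
#' @return List with elements `train`, `val`, `test` (subsets of `items`)
#'   and `index` (the integer assignment, 1 = train, 2 = val, 3 = test).
#' @export
split_dataset <- function(items, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (length(ratios) != 3L || any(ratios < 0))
    stop_config("ratios must be 3 non-negative numbers")
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_config("ratios must sum to 1, got ", sum(ratios))
  n <- length(items)
  if (n < 3L) stop_invalid("need at least 3 items to split")
  ord <- with_seed(seed, sample.int(n))
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  idx <- integer(n)
  idx[ord[seq_len(n_train)]] <- 1L
  idx[ord[n_train + seq_len(n_val)]] <- 2L
  if (n_train + n_val < n) idx[ord[(n_train + n_val + 1L):n]] <- 3L
  pick <- function(k) if (is.list(items)) items[idx == k] else items[idx == k]
  list(train = pick(1L), val = pick(2L), test = pick(3L), index = idx)
}

#' Write a patch set to disk as image/mask pairs
#'
#' Files are named `<source>_<row>_<col>.<ext>` and
#' `<source>_<row>_<col>_mask.<ext>`.
#'
#' @param ps A `patch_set`.
#' @param dir Output directory (created if missing).
#' @param ext Image format extension (default `"png"`).
#' @return Character vector of the image paths written (invisibly).
#' @export
write_patch_set <- function(ps, dir, ext = "png") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ps$patches))
  for (i in seq_along(ps$patches)) {
    p <- ps$patches[[i]]
    base <- sprintf("%s_%d_%d", p$source_id, p$row, p$col)
    paths[i] <- file.path(dir, paste0(base, ".", ext))
    write_image(p$image, paths[i])
    if (!is.null(p$mask))
      write_image(p$mask, file.path(dir, paste0(base, "_mask.", ext)))
  }
  invisible(paths)
}

#' Write split manifests as plain-text file lists
#'
#' @param split Result of [split_dataset()] applied to file paths.
#' @param dir Output directory.
#' @return Paths of the three manifest files (invisibly).
#' @export
write_split_manifests <- function(split, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(3)
  sets <- c("train", "val", "test")
  for (i in seq_along(sets)) {
    out[i] <- file.path(dir, paste0(sets[i], ".txt"))
    writeLines(unlist(split[[sets[i]]]), out[i])
  }
  invisible(out)
}
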