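# Synthetic rhizotron imagery: heterogeneous brownish soil backgrounds with
# thin, branching, variable-contrast root strokes and bit-exact paired
# masks, so every stage of the pipeline is testable without field data.

#' Synthetic-image configuration
#'
#' Defaults emulate the visual regime of field rhizotron imagery of fine
#' roots: 1-5 px wide strokes (sub-2-mm roots at the scanned resolution),
#' moderate root/soil contrast, and textured soil backgrounds.
#'
#' @param size Image side in pixels.
#' @param n_roots Number of primary root strokes.
#' @param width_range Stroke width interval in px (default `c(1, 5)`);
#'   must stay within `[1, size/4]`.
#' @param branch_prob Per-step probability that a stroke spawns a branch
#'   (default 0.02).
#' @param contrast Foreground-background mean intensity gap on the
#'   normalized scale, in `[0, 1]` (default 0.35).
#' @param noise_scale Amplitude of the background texture (default 0.08;
#'   0 gives a constant background).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(size = 256L, n_roots = 3L, width_range = c(1L, 5L),
                         branch_prob = 0.02, contrast = 0.35,
                         noise_scale = 0.08, seed = 0L) {
  if (size < 16L) stop_config("size must be >= 16")
  if (width_range[1] < 1L || width_range[2] > size / 4)
    stop_config("width_range must lie within [1, size/4]")
  if (contrast < 0 || contrast > 1) stop_config("contrast must be in [0, 1]")
  structure(list(size = as.integer(size), n_roots = as.integer(n_roots),
                 width_range = as.integer(width_range),
                 branch_prob = branch_prob, contrast = contrast,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "synth_config")
}

# Low-frequency value noise: coarse Gaussian grids upsampled bilinearly.
value_noise <- function(size, cells) {
  g <- matrix(stats::rnorm(cells * cells), cells, cells)
  M <- bilinear_map(size, cells)
  M %*% g %*% t(M)
}

#' Generate a soil-like background
#'
#' A brownish base color modulated by three octaves of low-frequency value
#' noise plus per-pixel speckle; reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return `size x size x 3` RGB array in `[0, 1]`.
#' @export
make_soil_background <- function(config = synth_config()) {
  with_seed(config$seed, {
    s <- config$size
    base <- c(0.45, 0.35, 0.26)              # wet-soil brown
    tex <- 0
    if (config$noise_scale > 0) {
      tex <- value_noise(s, max(2L, s %/% 32L)) * 0.6 +
             value_noise(s, max(3L, s %/% 8L)) * 0.3 +
             matrix(stats::rnorm(s * s), s, s) * 0.25
      tex <- tex * config$noise_scale
    }
    out <- array(0, c(s, s, 3L))
    for (c in 1:3) out[, , c] <- clamp(base[c] + tex * (1 + 0.2 * (c == 1)), 0, 1)
    out
  })
}

# Rasterize a disc of radius w/2 at integer centers into a logical matrix.
paint_disc <- function(m, r, c, width) {
  s <- nrow(m)
  rad <- max((width - 1) / 2, 0)
  ir <- max(1L, floor(r - rad)):min(s, ceiling(r + rad))
  ic <- max(1L, floor(c - rad)):min(s, ceiling(c + rad))
  for (rr in ir) for (cc in ic) {
    if ((rr - r)^2 + (cc - c)^2 <= rad^2 + 0.26) m[rr, cc] <- TRUE
  }
  m
}

walk_root <- function(mask, s, width, branch_prob, depth = 0L) {
  r <- stats::runif(1, 1, s)
  c <- stats::runif(1, 1, s)
  walk_from(mask, s, r, c, stats::runif(1, 0, 2 * pi), width, branch_prob,
            depth)
}

walk_from <- function(mask, s, r, c, theta, width, branch_prob, depth) {
  n_steps <- round(stats::runif(1, s / 4, s))
  for (i in seq_len(n_steps)) {
    theta <- theta + stats::rnorm(1, 0, 0.15)
    r <- r + sin(theta); c <- c + cos(theta)
    if (r < 1 || r > s || c < 1 || c > s) break
    mask <- paint_disc(mask, r, c, width)
    if (depth < 2L && stats::runif(1) < branch_prob) {
      dth <- stats::rnorm(1, 0.6, 0.17) * sample(c(-1, 1), 1)
      dth <- clamp(dth, -1.2, 1.2)       # bounded branch angle
      mask <- walk_from(mask, s, r, c, theta + dth,
                        max(1, width - 1), branch_prob, depth + 1L)
    }
  }
  mask
}

#' Draw branching root strokes on a background
#'
#' Smooth random-walk polylines with stochastic branching; stroke widths
#' sampled per root from `width_range`.  The mask is the exact set of
#' painted pixels (no anti-aliasing); on the image, foreground pixels are
#' brightened by `contrast` with mild smoothed variation so edges are not
#' artificially crisp.
#'
#' @param background `size x size x 3` array from [make_soil_background()].
#' @param config A [synth_config()].
#' @return List with `image` (RGB array) and `mask` (binary matrix).
#' @export
draw_roots <- function(background, config = synth_config()) {
  s <- config$size
  with_seed(derive_seed(config$seed, 1L), {
    mask <- matrix(FALSE, s, s)
    for (k in seq_len(config$n_roots)) {
      width <- sample(seq(config$width_range[1], config$width_range[2]), 1L)
      mask <- walk_root(mask, s, width, config$branch_prob)
    }
    image <- background
    if (any(mask)) {
      # roots render as pale yellowish strands above the soil tone
      gain <- config$contrast * (1 + 0.15 * matrix(stats::rnorm(s * s), s, s))
      tint <- c(1.0, 0.95, 0.75)
      for (c in 1:3) {
        ch <- image[, , c]
        ch[mask] <- clamp(ch[mask] + gain[mask] * tint[c], 0, 1)
        image[, , c] <- ch
      }
    }
    list(image = image, mask = mask * 1)
  })
}

#' Generate one synthetic image/mask pair
#'
#' @param config A [synth_config()].
#' @return List with `image` and `mask`.
#' @export
synth_pair <- function(config = synth_config()) {
  draw_roots(make_soil_background(config), config)
}

#' Write a synthetic dataset to disk
#'
#' `n` image/mask PNG pairs with per-sample seeds derived from
#' `config$seed`, plus a CSV manifest of paths and seeds; regeneration from
#' the manifest seeds reproduces identical files.
#'
#' @param n Number of pairs.
#' @param config A [synth_config()]; its `seed` is the master seed.
#' @param dir Output directory.
#' @return The manifest data frame (invisibly); written as
#'   `manifest.csv` in `dir`.
#' @export
make_dataset <- function(n, config = synth_config(), dir) {
  if (n < 1L) stop_config("n must be >= 1")
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  manifest <- data.frame(image = character(n), mask = character(n),
                         seed = numeric(n))
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, i + 1L)
    pair <- synth_pair(cfg_i)
    ip <- file.path(dir, sprintf("synth_%03d.png", i))
    mp <- file.path(dir, sprintf("synth_%03d_mask.png", i))
    write_image(pair$image, ip)
    write_image(pair$mask, mp)
    manifest[i, ] <- list(ip, mp, cfg_i$seed)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Published per-image root-length reference tables
#'
#' The packaged fixture: per-image fine-root lengths for the 10 rhizotron
#' test images, measured manually (line-intersect, mm) and from the
#' improved U-Net segmentation (px), by root order.
#'
#' @return List with data frames `manual` and `segmentation`, each with
#'   columns `image`, `order_1`, `order_2`, `order_3`, `total_length`.
#' @export
reference_root_lengths <- function() {
  dirp <- system.file("extdata", package = "rhizoseg")
  list(manual = read_length_table(file.path(dirp, "root_lengths_manual_mm.csv")),
       segmentation =
         read_length_table(file.path(dirp, "root_lengths_unet_px.csv")))
}

#' Published root-class F1 scores of the compared models
#'
#' Root F1 (%) of the improved U-Net and the three reference architectures
#' on the rhizotron test set, as published; consumed as plain numbers for
#' excess-ratio arithmetic.
#'
#' @return Data frame with columns `model` and `root_f1`.
#' @export
reference_root_f1 <- function() {
  p <- system.file("extdata", "root_f1_comparison.csv", package = "rhizoseg")
  utils::read.csv(p, stringsAsFactors = FALSE)
}
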