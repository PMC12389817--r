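# Shared fixtures, all built in code.

# A tiny training set of synthetic rhizotron patches.
make_tiny_set <- function(n = 8L, size = 64L, seed = 0L) {
  base <- synth_config(size = size, n_roots = 3L, contrast = 0.45,
                       noise_scale = 0.06, seed = seed)
  lapply(seq_len(n), function(i) {
    cfg <- base
    cfg$seed <- rhizoseg:::derive_seed(seed, i + 1L)
    p <- synth_pair(cfg)
    list(x = to_model_input(p$image, size), y = binarize_mask(p$mask * 255))
  })
}

tiny_model_config <- function(attention = "cbam", fusion = "upadd") {
  unet_config(stage_channels = c(8L, 16L, 32L, 64L), attention = attention,
              fusion = fusion, reduction_ratio = 4L)
}

# Smallest config that still has the full architecture; for shape tests.
micro_model_config <- function(attention = "cbam", fusion = "upadd") {
  unet_config(stage_channels = c(4L, 8L, 16L, 32L), attention = attention,
              fusion = fusion, reduction_ratio = 4L)
}

random_rgb <- function(h, w, seed = 1L) {
  rhizoseg:::with_seed(seed, array(stats::runif(h * w * 3), c(h, w, 3)))
}
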