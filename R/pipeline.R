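# Single entry point wiring all stages with a YAML config, versioned run
# directories and plain-text logging.

#' Default pipeline configuration
#'
#' Every field has a default; unknown keys in a user config are rejected.
#' The `full` profile mirrors the published full-scale protocol (batch 16,
#' 80 epochs, 512-px inputs, stage channels 64-512) and is GPU-scale: it is
#' not exercised by the test suite.
#'
#' @param profile `"tiny"` (CPU-friendly, see [tiny_profile()]) or
#'   `"full"`.
#' @return Nested configuration list.
#' @export
default_config <- function(profile = c("tiny", "full")) {
  profile <- match.arg(profile)
  if (profile == "tiny") return(tiny_profile())
  list(
    run_id = "run",
    out_dir = "runs",
    seed = 0L,
    synth = list(n = 32L, size = 512L, n_roots = 4L, contrast = 0.35,
                 noise_scale = 0.08),
    data = list(patch = 512L, stride = 256L, ratios = c(0.7, 0.2, 0.1)),
    input = list(size = 512L, colorspace = "hsv"),
    augment = list(prob = 0.3, jitter = 0.5, crop_scale = c(0.2, 1),
                   rot_limit = 90),
    model = list(stage_channels = c(64L, 128L, 256L, 512L),
                 attention = "cbam", fusion = "upadd", reduction = 16L),
    loss = list(weights = c(0.4, 0.4, 0.2), focal_alpha = 0.9,
                focal_gamma = 2.5, dice_smooth = 1, edge_dilate = 1L),
    train = list(batch_size = 16L, epochs = 80L, lr0 = 1e-4,
                 weight_decay = 1e-4, max_steps = Inf),
    eval = list(thresholds = seq(0.1, 0.9, by = 0.1))
  )
}

#' Built-in tiny profile
#'
#' A configuration that exercises every module on one CPU in minutes:
#' 64 x 64 synthetic inputs, stage channels 8-64, attention reduction 4,
#' at most 200 optimization steps with a learning rate suited to
#' small-batch overfitting.
#'
#' @return Nested configuration list.
#' @export
tiny_profile <- function() {
  cfg <- default_config("full")
  cfg$synth <- list(n = 8L, size = 64L, n_roots = 3L, contrast = 0.45,
                    noise_scale = 0.06)
  cfg$data$patch <- 64L
  cfg$data$stride <- 64L
  cfg$input$size <- 64L
  cfg$model <- list(stage_channels = c(8L, 16L, 32L, 64L),
                    attention = "cbam", fusion = "upadd", reduction = 4L)
  cfg$train <- list(batch_size = 8L, epochs = 200L, lr0 = 3e-3,
                    weight_decay = 1e-4, max_steps = 200L)
  cfg
}

# Recursively check cfg against the schema of defaults; unknown keys are
# configuration errors naming the offending path.
check_config_keys <- function(cfg, defaults, path = character(0)) {
  if (!is.list(cfg)) return(invisible(TRUE))
  for (nm in names(cfg)) {
    full <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(defaults))
      stop_config("unknown configuration key: ", full)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      check_config_keys(cfg[[nm]], defaults[[nm]], c(path, nm))
  }
  invisible(TRUE)
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(cfg[[nm]]) &&
                          !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  defaults
}

log_line <- function(con, level, ...) {
  msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 level, paste0(...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

samples_from_dir <- function(dir, input_size, colorspace) {
  man <- file.path(dir, "manifest.csv")
  files <- if (file.exists(man)) utils::read.csv(man) else {
    imgs <- list.files(dir, pattern = "\\d\\.(png|ppm)$", full.names = TRUE)
    imgs <- imgs[!grepl("_mask\\.", imgs)]
    data.frame(image = imgs,
               mask = sub("\\.(png|ppm)$", "_mask.\\1", imgs))
  }
  lapply(seq_len(nrow(files)), function(i) {
    img <- read_image(files$image[i])
    msk <- read_image(files$mask[i])
    list(x = to_model_input(img, input_size, colorspace),
         y = binarize_mask(if (length(dim(msk)) == 3L)
           msk[, , 1] else msk))
  })
}

#' Run a pipeline stage
#'
#' Commands: `"synth"` (generate a dataset), `"train"`, `"predict"`,
#' `"evaluate"`, `"traits"` (root lengths from masks), `"agree"`
#' (correlation between two length tables).  Artifacts land in
#' `<out_dir>/<run_id>/{config.yaml, logs/, checkpoints/, reports/}` and the
#' effective configuration (defaults resolved) is always written back, so a
#' run is reconstructible from its directory.
#'
#' @param command One of the stage names above.
#' @param config Nested list overriding [default_config()] fields
#'   (unknown keys rejected), or a path to a YAML file.
#' @param args Stage-specific arguments: `data_dir`, `checkpoint`,
#'   `pretrained`, `masks_dir`, `table_a`, `table_b`.
#' @return Stage result (invisibly); artifacts on disk.
#' @export
run_pipeline <- function(command = c("synth", "train", "predict", "evaluate",
                                     "traits", "agree"),
                         config = list(), args = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config("tiny")
  check_config_keys(config, defaults)
  cfg <- merge_config(defaults, config)
  run_dir <- file.path(cfg$out_dir, cfg$run_id)
  for (d in c("logs", "checkpoints", "reports"))
    dir.create(file.path(run_dir, d), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(run_dir, "config.yaml"))
  logf <- file(file.path(run_dir, "logs", paste0(command, ".log")), "a")
  on.exit(close(logf))
  log_line(logf, "INFO", "stage=", command, " run=", cfg$run_id,
           " seed=", cfg$seed)

  result <- switch(command,
    synth = {
      sc <- synth_config(size = cfg$synth$size, n_roots = cfg$synth$n_roots,
                         contrast = cfg$synth$contrast,
                         noise_scale = cfg$synth$noise_scale,
                         seed = cfg$seed)
      man <- make_dataset(cfg$synth$n, sc, file.path(run_dir, "data"))
      log_line(logf, "INFO", "wrote ", nrow(man), " image/mask pairs")
      man
    },
    train = {
      data_dir <- args$data_dir %||% file.path(run_dir, "data")
      samples <- samples_from_dir(data_dir, cfg$input$size,
                                  cfg$input$colorspace)
      sp <- split_dataset(samples, cfg$data$ratios, seed = cfg$seed)
      mcfg <- unet_config(stage_channels = cfg$model$stage_channels,
                          attention = cfg$model$attention,
                          fusion = cfg$model$fusion,
                          reduction_ratio = cfg$model$reduction)
      tcfg <- train_config(batch_size = cfg$train$batch_size,
                           epochs = cfg$train$epochs, lr0 = cfg$train$lr0,
                           weight_decay = cfg$train$weight_decay,
                           seed = cfg$seed, max_steps = cfg$train$max_steps,
                           loss_weights = loss_weights(cfg$loss$weights[1],
                                                       cfg$loss$weights[2],
                                                       cfg$loss$weights[3]),
                           focal = focal_params(cfg$loss$focal_alpha,
                                                cfg$loss$focal_gamma))
      fit <- if (!is.null(args$pretrained)) {
        log_line(logf, "INFO", "fine-tuning from ", args$pretrained)
        fine_tune_unet(args$pretrained, sp$train, sp$val, tcfg,
                       expect_config = mcfg)
      } else {
        model <- unet_init(mcfg, seed = cfg$seed)
        train_unet(model, sp$train, sp$val, tcfg)
      }
      save_checkpoint(fit$model, file.path(run_dir, "checkpoints", "final.rds"),
                      epoch = nrow(fit$history), seed = cfg$seed)
      save_checkpoint(fit$best, file.path(run_dir, "checkpoints", "best.rds"),
                      epoch = nrow(fit$history), seed = cfg$seed)
      utils::write.csv(fit$history,
                       file.path(run_dir, "reports", "history.csv"),
                       row.names = FALSE)
      log_line(logf, "INFO", "final train loss ",
               round(utils::tail(fit$history$train_loss, 1), 4))
      fit
    },
    predict = {
      ck <- load_checkpoint(args$checkpoint %||%
                              file.path(run_dir, "checkpoints", "best.rds"))
      data_dir <- args$data_dir %||% file.path(run_dir, "data")
      samples <- samples_from_dir(data_dir, cfg$input$size,
                                  cfg$input$colorspace)
      preds <- unet_predict(ck$model, lapply(samples, `[[`, "x"))
      pd <- file.path(run_dir, "predictions")
      dir.create(pd, showWarnings = FALSE)
      for (i in seq_along(preds)) {
        write_image(spatial_matrix(preds[[i]]),
                    file.path(pd, sprintf("prob_%03d.png", i)))
        if (!is.null(args$threshold))
          write_image((spatial_matrix(preds[[i]]) >= args$threshold) * 1,
                      file.path(pd, sprintf("mask_%03d.png", i)))
      }
      log_line(logf, "INFO", "wrote ", length(preds), " probability maps")
      preds
    },
    evaluate = {
      ck <- load_checkpoint(args$checkpoint %||%
                              file.path(run_dir, "checkpoints", "best.rds"))
      data_dir <- args$data_dir %||% file.path(run_dir, "data")
      samples <- samples_from_dir(data_dir, cfg$input$size,
                                  cfg$input$colorspace)
      preds <- unet_predict(ck$model, lapply(samples, `[[`, "x"))
      sw <- threshold_sweep(preds, lapply(samples, `[[`, "y"),
                            cfg$eval$thresholds)
      rep <- list(threshold = sw$threshold,
                  root = as.list(round(sw$report$root * 100, 2)),
                  background = as.list(round(sw$report$background * 100, 2)),
                  mean = as.list(round(sw$report$mean * 100, 2)))
      jsonlite::write_json(rep, file.path(run_dir, "reports", "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line(logf, "INFO", "best threshold ", sw$threshold, ", mIoU ",
               round(sw$report$mean[["iou"]], 4))
      sw
    },
    traits = {
      masks <- list.files(args$masks_dir %||% file.path(run_dir, "data"),
                          pattern = "_mask\\.(png|ppm|pgm)$",
                          full.names = TRUE)
      lens <- vapply(masks, function(p)
        skeleton_length(read_image(p) > 0.5), numeric(1))
      df <- data.frame(image = basename(masks), order_1 = NA, order_2 = NA,
                       order_3 = NA, total_length = unname(lens))
      utils::write.csv(df, file.path(run_dir, "reports", "lengths.csv"),
                       row.names = FALSE)
      log_line(logf, "INFO", "measured ", nrow(df), " masks")
      df
    },
    agree = {
      ta <- if (is.null(args$table_a)) reference_root_lengths()$manual
            else read_length_table(args$table_a)
      tb <- if (is.null(args$table_b)) reference_root_lengths()$segmentation
            else read_length_table(args$table_b)
      ag <- length_table_agreement(ta, tb)
      out <- lapply(ag, function(a)
        list(r = a$r, r_squared = a$r_squared, p_value = a$p_value,
             significant_after_bonferroni = a$significant_after_bonferroni))
      jsonlite::write_json(out, file.path(run_dir, "reports", "agreement.json"),
                           auto_unbox = TRUE, digits = NA)
      for (nm in names(ag))
        log_line(logf, "INFO", nm, ": r=", round(ag[[nm]]$r, 3),
                 " p=", signif(ag[[nm]]$p_value, 3))
      ag
    }
  )
  invisible(result)
}
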