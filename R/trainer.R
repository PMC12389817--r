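# Training loop: AdamW with decoupled weight decay, cosine-annealed
# learning rate stepped once per epoch, per-epoch validation threshold
# sweep, best-checkpoint retention, and transfer-learning fine-tuning.

#' Training configuration
#'
#' Defaults follow the reference protocol: batch 16, 80 epochs, AdamW with
#' lr 1e-4, weight decay 1e-4, betas (0.9, 0.999), cosine annealing with
#' `T_max = epochs`.
#'
#' @param batch_size Samples per optimization step.
#' @param epochs Training epochs (also the scheduler period).
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param betas AdamW momentum parameters.
#' @param eta_min Final learning rate of the cosine schedule.
#' @param seed RNG seed for shuffling (and any augmentation draws).
#' @param max_steps Optional cap on total optimization steps (handy for
#'   small-scale overfitting runs); `Inf` disables.
#' @param loss_weights,focal A [loss_weights()] and [focal_params()] pair.
#' @param val_every Run the validation sweep every this many epochs.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, epochs = 80L, lr0 = 1e-4,
                         weight_decay = 1e-4, betas = c(0.9, 0.999),
                         eta_min = 0, seed = 0L, max_steps = Inf,
                         loss_weights = rhizoseg::loss_weights(),
                         focal = focal_params(), val_every = 1L) {
  if (epochs < 1L) stop_config("epochs must be >= 1")
  if (lr0 <= 0) stop_config("lr0 must be positive")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 weight_decay = weight_decay, betas = betas,
                 eta_min = eta_min, seed = as.integer(seed),
                 max_steps = max_steps, loss_weights = loss_weights,
                 focal = focal, val_every = as.integer(val_every)),
            class = "train_config")
}

#' Cosine-annealed learning rate
#'
#' `eta_min + (lr0 - eta_min) * (1 + cos(pi * t / T_max)) / 2`; epochs past
#' `T_max` clamp to `eta_min`.
#'
#' @param t Epoch index (0-based).
#' @param lr0 Initial learning rate.
#' @param T_max Annealing period in epochs.
#' @param eta_min Floor learning rate.
#' @return The learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, lr0 = 1e-4, T_max = 80L, eta_min = 0) {
  if (t < 0) stop_invalid("epoch must be >= 0")
  if (t > T_max) return(eta_min)
  eta_min + 0.5 * (lr0 - eta_min) * (1 + cos(pi * t / T_max))
}

adamw_new <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),  # zeros, shape-preserving
       v = lapply(params, function(p) p * 0))
}

adamw_step <- function(opt, params, grads, lr, betas, weight_decay,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    upd <- (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(opt = opt, params = params)
}

stack_batch <- function(set, idx) {
  d <- dim(set[[idx[1]]]$x)
  xb <- array(0, c(d, length(idx)))
  yb <- array(0, c(dim(set[[idx[1]]]$y), length(idx)))
  for (k in seq_along(idx)) {
    xb[, , , k] <- set[[idx[k]]]$x
    yb[, , , k] <- set[[idx[k]]]$y
  }
  list(x = xb, y = yb)
}

run_epoch <- function(model, opt, set, config, lr) {
  n <- length(set)
  ord <- sample.int(n)
  total <- 0
  count <- 0L
  i <- 1L
  while (i <= n) {
    idx <- ord[i:min(i + config$batch_size - 1L, n)]
    b <- stack_batch(set, idx)
    fw <- unet_forward(model, b$x, training = TRUE, with_tape = TRUE)
    L <- total_loss(fw$out$value, b$y, config$loss_weights, config$focal,
                    grad = TRUE)
    if (!is.finite(L$value))
      stop("non-finite training loss (", L$value, ") at step ", opt$t + 1L,
           "; check learning rate and inputs")
    ad_backward(fw$tape, fw$out, L$grad)
    grads <- lapply(fw$pnodes, function(nd) nd$grad)
    st <- adamw_step(opt, model$params, grads, lr, config$betas,
                     config$weight_decay)
    opt <- st$opt
    model$params <- st$params
    total <- total + L$value * length(idx)
    count <- count + length(idx)
    i <- i + config$batch_size
    if (opt$t >= config$max_steps) break
  }
  list(model = model, opt = opt, loss = total / count)
}

validate <- function(model, val_set, config) {
  probs <- vector("list", length(val_set))
  gts <- vector("list", length(val_set))
  losses <- numeric(length(val_set))
  for (j in seq_along(val_set)) {
    x <- val_set[[j]]$x
    dim(x) <- c(dim(x), 1L)
    p <- unet_forward(model, x, training = FALSE)
    probs[[j]] <- p[, , , 1, drop = FALSE]
    dim(probs[[j]]) <- dim(probs[[j]])[1:3]
    gts[[j]] <- val_set[[j]]$y
    losses[j] <- total_loss(probs[[j]], gts[[j]], config$loss_weights,
                            config$focal)
  }
  sw <- threshold_sweep(probs, gts)
  list(loss = mean(losses), sweep = sw)
}

#' Train an improved U-Net
#'
#' Plain training with AdamW, per-epoch cosine annealing, the hybrid
#' Dice/focal/edge loss, and a validation threshold sweep each epoch; the
#' checkpoint with the best validation mIoU is retained alongside the final
#' state.
#'
#' @param model A model from [unet_init()] (or a loaded checkpoint's model).
#' @param train_set,val_set Lists of samples, each `list(x = (3,H,W) array,
#'   y = (1,H,W) binary array)`.  `val_set` may be `NULL` to skip
#'   validation.
#' @param config A [train_config()].
#' @return List with `model` (final), `best` (best-validation model, or the
#'   final model when no validation), `history` (per-epoch data frame with
#'   train loss, validation loss, learning rate, validation mIoU and
#'   selected threshold), `transfer` flag.
#' @export
train_unet <- function(model, train_set, val_set = NULL,
                       config = train_config()) {
  if (length(train_set) == 0L) stop_config("empty training set")
  with_seed(config$seed, {
    opt <- adamw_new(model$params)
    hist <- data.frame()
    best <- list(miou = -Inf, model = model)
    for (ep in seq_len(config$epochs)) {
      lr <- cosine_lr(ep - 1L, config$lr0, config$epochs, config$eta_min)
      r <- run_epoch(model, opt, train_set, config, lr)
      model <- r$model
      opt <- r$opt
      val_loss <- NA_real_; val_miou <- NA_real_; thr <- NA_real_
      if (!is.null(val_set) && length(val_set) &&
          (ep %% config$val_every == 0L || ep == config$epochs)) {
        v <- validate(model, val_set, config)
        val_loss <- v$loss
        val_miou <- v$sweep$report$mean[["iou"]]
        thr <- v$sweep$threshold
        if (val_miou > best$miou) best <- list(miou = val_miou, model = model)
      }
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = r$loss,
                                     val_loss = val_loss, lr = lr,
                                     val_miou = val_miou, threshold = thr))
      if (opt$t >= config$max_steps) break
    }
    if (!is.finite(best$miou)) best$model <- model
    list(model = model, best = best$model, history = hist, transfer = FALSE)
  })
}

#' Fine-tune from a checkpoint (transfer learning)
#'
#' Loads all weights from the checkpoint (no layers frozen, fresh optimizer
#' state) and continues training on new data.
#'
#' @param checkpoint A checkpoint path, a model object, or a [train_unet()]
#'   result (its `model` element is used).
#' @param train_set,val_set New training/validation samples.
#' @param config A [train_config()].
#' @param expect_config Optional `unet_config` the caller's pipeline is
#'   built for; a mismatch raises an error listing the differing fields.
#' @return As [train_unet()], with `transfer = TRUE`.
#' @export
fine_tune_unet <- function(checkpoint, train_set, val_set = NULL,
                           config = train_config(), expect_config = NULL) {
  model <- if (is.character(checkpoint)) load_checkpoint(checkpoint)$model
           else if (!is.null(checkpoint$params)) checkpoint
           else checkpoint$model
  if (!is.null(expect_config)) check_config_compat(model$config, expect_config)
  out <- train_unet(model, train_set, val_set, config)
  out$transfer <- TRUE
  out
}

#' Compare two model configurations field by field
#'
#' @param a,b `unet_config` objects.
#' @return Invisibly `TRUE`; raises an error listing every differing field.
#' @export
check_config_compat <- function(a, b) {
  fields <- union(names(a), names(b))
  diffs <- fields[!vapply(fields, function(f) identical(a[[f]], b[[f]]),
                          logical(1))]
  if (length(diffs))
    stop_config("incompatible model configuration; differing fields: ",
                paste(diffs, collapse = ", "))
  invisible(TRUE)
}

#' Save a model checkpoint
#'
#' A single-file archive (RDS) with format version, weights, batch-norm
#' running moments, configuration, and training metadata.
#'
#' @param model The model object.
#' @param path Output file path.
#' @param epoch,seed Metadata recorded alongside the weights.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_,
                            seed = model$seed) {
  obj <- list(format = "rhizoseg-checkpoint", version = 1L,
              config = model$config, params = model$params,
              bn = as.list(model$bn),
              meta = list(epoch = epoch, seed = seed,
                          created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @param expect_config Optional `unet_config`; when given, an
#'   incompatibility error lists every differing field.
#' @return List with `model` and `meta`.
#' @export
load_checkpoint <- function(path, expect_config = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rhizoseg-checkpoint"))
    stop_invalid("not a rhizoseg checkpoint: ", path)
  if (!is.null(expect_config)) check_config_compat(obj$config, expect_config)
  bn <- new.env(parent = emptyenv())
  for (nm in names(obj$bn)) bn[[nm]] <- obj$bn[[nm]]
  list(model = list(config = obj$config, params = obj$params, bn = bn,
                    seed = obj$meta$seed),
       meta = obj$meta)
}
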