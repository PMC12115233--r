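# Training loop: AdamW on the hand-written backpropagation, per-epoch
# validation, run logging, and checkpointing.

#' Training configuration
#'
#' Defaults follow the study settings: AdamW, initial learning rate 0.01,
#' batch size 16, momentum (beta1) 0.937, weight decay 0.0005.  The
#' "momentum parameter" is mapped to AdamW's beta1 (beta2 stays 0.999).
#'
#' @param lr Initial learning rate (> 0).
#' @param batch_size Images per optimizer step (>= 1).
#' @param epochs Training epochs (>= 1).
#' @param beta1,beta2 AdamW moment coefficients.
#' @param weight_decay Decoupled weight decay coefficient.
#' @param loss Box loss: `"cmiou"` (default) or `"ciou"`.
#' @param loss_weights Named weights for the `cls`, `box`, `obj` terms.
#' @param mosaic Apply mosaic augmentation to training batches.
#' @param lr_schedule `"constant"` (default) or `"cosine"`.
#' @param warmup_epochs Linear learning-rate warmup over this many initial
#'   epochs (default 3), stabilizing the first optimizer steps.
#' @param clip_norm Global gradient-norm clipping threshold (default 10;
#'   `Inf` disables).
#' @param eval_every Validate every this many epochs (the final epoch is
#'   always validated when validation data exist).
#' @param seed Seed controlling initialization, shuffling, and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 0.01, batch_size = 16L, epochs = 50L,
                         beta1 = 0.937, beta2 = 0.999, weight_decay = 5e-4,
                         loss = c("cmiou", "ciou"),
                         loss_weights = c(cls = 0.5, box = 5, obj = 1),
                         mosaic = TRUE, lr_schedule = c("constant", "cosine"),
                         warmup_epochs = 3L, clip_norm = 10,
                         eval_every = 1L, seed = 0L) {
  loss <- match.arg(loss)
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr >= 0, batch_size >= 1, epochs >= 1, warmup_epochs >= 0,
            clip_norm > 0,
            all(c("cls", "box", "obj") %in% names(loss_weights)))
  structure(list(optimizer = "adamw", lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, loss = loss,
                 loss_weights = loss_weights, mosaic = mosaic,
                 lr_schedule = lr_schedule, warmup_epochs = as.integer(warmup_epochs),
                 clip_norm = clip_norm, eval_every = as.integer(eval_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter-tree helpers (walk the gradient tree's shape) ---------------

tree_zero <- function(g) {
  if (is.list(g)) lapply(g, tree_zero) else g * 0
}

adamw_step <- function(p, g, opt, lr, tc) {
  if (is.null(opt$m)) {
    opt$m <- tree_zero(g); opt$v <- tree_zero(g)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - tc$beta1^opt$t; bc2 <- 1 - tc$beta2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(g)) {
      for (nm in names(g)) {
        if (!length(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- tc$beta1 * m + (1 - tc$beta1) * g
    v <- tc$beta2 * v + (1 - tc$beta2) * g * g
    p <- p - lr * ((m / bc1) / (sqrt(v / bc2) + 1e-8) + tc$weight_decay * p)
    list(p = p, m = m, v = v)
  }
  r <- upd(p, g, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(p = r$p, opt = opt)
}

tree_scale <- function(g, f) {
  if (is.list(g)) lapply(g, tree_scale, f = f) else g * f
}

tree_add <- function(a, b) {
  if (is.list(b)) {
    for (nm in names(b)) a[[nm]] <- tree_add(a[[nm]], b[[nm]])
    a
  } else if (is.null(a)) b else a + b
}

as_target <- function(li, sz) {
  b <- ann_to_boxes(li$annotations, sz, sz)
  list(boxes = b, class = li$annotations$class)
}

prep_image <- function(li, sz) {
  if (nrow(li$image) != sz || ncol(li$image) != sz) li <- letterbox_resize(li, sz)
  li
}

#' Train the detector
#'
#' Runs assignment, the composite loss (CMIoU or CIoU box term), and AdamW
#' steps over mini-batches; validates on `val_data` every
#' `tcfg$eval_every` epochs; keeps the checkpoint with the best validation
#' mAP50 as well as the last.  Fully seeded: identical seeds and data give
#' identical run logs.
#'
#' @param data Training data: list of `labeled_image` objects or a dataset
#'   directory written by [generate_dataset()].
#' @param cfg A [detector_config()].
#' @param tcfg A [train_config()].
#' @param val_data Optional validation data (list of `labeled_image`); when
#'   `data` is a directory its `val` split is used automatically.
#' @param verbose Print one line per epoch.
#' @return A `rootvoid_detector`: list with `model` (last), `best_model`,
#'   `runlog` (one row per epoch), `train_cfg`, `cfg`.
#' @export
train_detector <- function(data, cfg = detector_config(preset = "nano", input_size = 160L),
                           tcfg = train_config(), val_data = NULL, verbose = FALSE) {
  if (is.character(data)) {
    dir <- data
    data <- load_dataset(dir, "train")
    if (is.null(val_data)) {
      val_data <- tryCatch(load_dataset(dir, "val"), error = function(e) NULL)
    }
  }
  stopifnot(length(data) >= 1)
  sz <- cfg$input_size
  data <- lapply(data, prep_image, sz = sz)
  if (!is.null(val_data)) val_data <- lapply(val_data, prep_image, sz = sz)
  model <- build_detector(cfg, seed = tcfg$seed)
  opt <- list(m = NULL, v = NULL, t = 0L)
  n <- length(data)
  logrows <- vector("list", tcfg$epochs)
  best <- list(map50 = -Inf, model = NULL)
  t0 <- Sys.time()
  with_seed(tcfg$seed + 1L, {
    for (epoch in seq_len(tcfg$epochs)) {
      lr <- if (tcfg$lr_schedule == "cosine") {
        e0 <- max(0, epoch - 1 - tcfg$warmup_epochs)
        tcfg$lr * (0.5 * (1 + cos(pi * e0 / max(1, tcfg$epochs - 1 - tcfg$warmup_epochs)))) + 1e-6
      } else tcfg$lr
      if (tcfg$warmup_epochs > 0 && epoch <= tcfg$warmup_epochs) {
        lr <- lr * epoch / (tcfg$warmup_epochs + 1)
      }
      ord <- if (n > 1) sample.int(n) else 1L
      comp <- c(total = 0, cls = 0, box = 0, obj = 0)
      nb <- 0L
      for (start in seq(1L, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        items <- lapply(idx, function(i) {
          if (tcfg$mosaic && stats::runif(1) < 0.5 && n >= 4) {
            src <- c(i, sample.int(n, 3L))
            mosaic_augment(data[src], out_size = sz,
                           seed = sample.int(2147483646L, 1L))
          } else data[[i]]
        })
        x <- array(0, dim = c(sz, sz, 1L, length(items)))
        for (j in seq_along(items)) x[, , 1, j] <- items[[j]]$image
        fw <- forward_full(model, x, train = TRUE)
        model$state <- fw$state
        targets <- lapply(items, as_target, sz = sz)
        ls <- detection_loss(fw[c("p3", "p4", "p5")], targets, cfg,
                             loss = tcfg$loss, weights = tcfg$loss_weights)
        if (!is.finite(ls$total)) {
          stop("non-finite loss at epoch ", epoch, ", batch images [",
               paste(vapply(items, `[[`, "", "id"), collapse = ", "), "]")
        }
        grads <- backward_full(ls$draw$p3, ls$draw$p4, ls$draw$p5, fw$cache,
                               use_resconv = cfg$use_resconv)
        if (is.finite(tcfg$clip_norm)) {
          gn <- sqrt(sum(rapply(grads, function(v) sum(v * v), how = "unlist")))
          if (gn > tcfg$clip_norm) grads <- tree_scale(grads, tcfg$clip_norm / gn)
        }
        if (lr > 0) {
          st <- adamw_step(model$params, grads, opt, lr, tcfg)
          model$params <- st$p; opt <- st$opt
        }
        comp <- comp + c(ls$total, ls$cls, ls$box, ls$obj)
        nb <- nb + 1L
      }
      comp <- comp / nb
      do_eval <- !is.null(val_data) &&
        (epoch %% tcfg$eval_every == 0L || epoch == tcfg$epochs)
      ev <- if (do_eval) evaluate_detector(model, val_data) else NULL
      logrows[[epoch]] <- data.frame(
        epoch = epoch, lr = lr, loss = comp[["total"]], cls = comp[["cls"]],
        box = comp[["box"]], obj = comp[["obj"]],
        val_map50 = if (do_eval) ev$map50 else NA_real_,
        val_map50_95 = if (do_eval) ev$map50_95 else NA_real_,
        val_precision = if (do_eval) ev$precision else NA_real_,
        val_recall = if (do_eval) ev$recall else NA_real_,
        wall_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
      if (do_eval && is.finite(ev$map50) && ev$map50 > best$map50) {
        best <- list(map50 = ev$map50, model = model)
      }
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f (cls %.4f box %.4f obj %.4f)%s",
                        epoch, comp[["total"]], comp[["cls"]], comp[["box"]],
                        comp[["obj"]],
                        if (do_eval) sprintf("  val mAP50 %.3f", ev$map50) else ""))
      }
    }
  })
  structure(list(model = model,
                 best_model = best$model %||% model,
                 runlog = do.call(rbind, logrows),
                 train_cfg = tcfg, cfg = cfg),
            class = "rootvoid_detector")
}

#' Evaluate a model on labeled data
#'
#' Decodes with a low confidence floor (0.05) so the full precision-recall
#' curve is populated, applies NMS, and computes mAP50 / mAP50-95 plus the
#' F1-optimal operating precision and recall.
#'
#' @param model A `rootvoid_model` or `rootvoid_detector` (its last model).
#' @param data List of `labeled_image` objects or a dataset directory
#'   (its `val` split).
#' @param conf_floor Decoding confidence floor (default 0.05).
#' @return An `eval_report` (see [map_over_thresholds()]).
#' @export
evaluate_detector <- function(model, data, conf_floor = 0.05) {
  if (inherits(model, "rootvoid_detector")) model <- model$model
  if (is.character(data)) data <- load_dataset(data, "val")
  if (!length(data)) stop("empty evaluation set")
  cfg <- model$cfg
  sz <- cfg$input_size
  data <- lapply(data, prep_image, sz = sz)
  if (any(vapply(data, function(li) nrow(li$annotations) > 0 &&
                 any(!li$annotations$class %in% (seq_len(cfg$nc) - 1L)), logical(1)))) {
    stop("class mismatch: data contain class ids outside the model's ",
         cfg$nc, "-class vocabulary")
  }
  dets <- list(); gts <- list()
  bs <- 8L
  for (start in seq(1L, length(data), by = bs)) {
    idx <- start:min(start + bs - 1L, length(data))
    x <- array(0, dim = c(sz, sz, 1L, length(idx)))
    for (j in seq_along(idx)) x[, , 1, j] <- data[[idx[j]]]$image
    raw <- forward_full(model, x, train = FALSE, keep_cache = FALSE)
    dec <- decode_predictions(raw[c("p3", "p4", "p5")], cfg, conf_thresh = conf_floor)
    for (j in seq_along(idx)) {
      li <- data[[idx[j]]]
      d <- nms(dec[[j]], cfg$nms_iou)
      if (nrow(d)) dets[[length(dets) + 1L]] <- cbind(image = li$id, d)
      if (nrow(li$annotations)) {
        b <- ann_to_boxes(li$annotations, sz, sz)
        gts[[length(gts) + 1L]] <- data.frame(image = li$id,
                                              class = li$annotations$class,
                                              x1 = b[, 1], y1 = b[, 2],
                                              x2 = b[, 3], y2 = b[, 4])
      }
    }
  }
  dets <- if (length(dets)) do.call(rbind, dets) else NULL
  gts <- if (length(gts)) do.call(rbind, gts) else NULL
  map_over_thresholds(dets, gts)
}

#' Save / load a detector checkpoint
#'
#' The checkpoint holds parameters, BN state, configuration, seed, run log,
#' and training configuration; loading then evaluating reproduces the
#' pre-save evaluation exactly.
#'
#' @param det A `rootvoid_detector` (or `rootvoid_model`).
#' @param path File path (RDS).
#' @export
save_checkpoint <- function(det, path) {
  saveRDS(det, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Desk-scale learning demonstration
#'
#' Generates the fixed easy phantom study (64 training and 16 validation
#' images at 160 x 160, high contrast, low noise, fixed data seeds), trains
#' the nano detector for 50 epochs with the CMIoU box loss, cosine learning
#' rate 0.003 with 3-epoch warmup, batch 16, and no mosaic, and validates on
#' the held-out images.
#'
#' @param train_seed Seed controlling initialization and shuffling.
#' @param epochs Training epochs (default 50).
#' @param verbose Print per-epoch progress.
#' @return The fitted `rootvoid_detector`; its run log's last row carries
#'   the validation mAP50.
#' @export
demo_run <- function(train_seed = 1L, epochs = 50L, verbose = FALSE) {
  spec <- phantom_spec_easy()
  train <- lapply(seq_len(spec$n_train), function(i) {
    generate_phantom(spec, seed = 1000L + i, id = sprintf("train_%03d", i))
  })
  val <- lapply(seq_len(spec$n_val), function(i) {
    generate_phantom(spec, seed = 9000L + i, id = sprintf("val_%03d", i))
  })
  cfg <- detector_config(preset = "nano", input_size = 160L)
  tcfg <- train_config(lr = 0.003, lr_schedule = "cosine", epochs = as.integer(epochs),
                       batch_size = 16L, mosaic = FALSE, eval_every = as.integer(epochs),
                       seed = as.integer(train_seed))
  train_detector(train, cfg, tcfg, val_data = val, verbose = verbose)
}
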