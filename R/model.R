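# The scaled-down anchor-free detector: residual-convolution backbone
# (strides 2..32), FPN top-down + PAN bottom-up neck, three detection heads
# at strides 8/16/32, with the attention-augmented fusion block immediately
# before the stride-8 (small-object) head.

#' Detector configuration
#'
#' @param input_size Square input side in px; must be divisible by 32 and by
#'   `8 * S` (so the stride-8 grid tokenizes evenly).
#' @param width Channel width multiplier (1 = the reference "nano"-times-two
#'   scale; the `"nano"` preset uses 0.5).
#' @param nc Number of classes (default 1: "void").
#' @param S Tokens per side in the attention block (default 4).
#' @param heads Attention heads (default 1).
#' @param conf_thresh Confidence threshold for decoded detections.
#' @param nms_iou IoU threshold for non-maximum suppression.
#' @param in_channels Input image channels (1 = grayscale).
#' @param use_resconv Use residual convolution backbone blocks; `FALSE`
#'   substitutes plain conv + BN + SiLU blocks (ablation switch).
#' @param use_tokatt Apply the tokenized-attention stage in the fused block
#'   before the stride-8 head; `FALSE` leaves the plain CSP fusion
#'   (ablation switch).
#' @param preset `"nano"` applies the CPU-scale defaults (width 0.5).
#' @return A `detector_config` list, including the per-stage channel plan.
#' @export
detector_config <- function(input_size = 640L, width = 1, nc = 1L, S = 4L,
                            heads = 1L, conf_thresh = 0.25, nms_iou = 0.45,
                            in_channels = 1L, use_resconv = TRUE,
                            use_tokatt = TRUE, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "nano")
    width <- 0.5
  }
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) {
    stop("input_size must be divisible by 32 (largest stride), got ", input_size)
  }
  if ((input_size %/% 8L) %% S != 0L) {
    stop("the stride-8 grid (", input_size %/% 8L, ") must be divisible by S = ", S)
  }
  ch <- pmax(4L, as.integer(round(width * c(16L, 32L, 48L, 64L, 96L))))
  structure(list(input_size = input_size, width = width, nc = as.integer(nc),
                 S = as.integer(S), heads = as.integer(heads),
                 conf_thresh = conf_thresh, nms_iou = nms_iou,
                 in_channels = as.integer(in_channels),
                 use_resconv = isTRUE(use_resconv), use_tokatt = isTRUE(use_tokatt),
                 channels = ch, neck_channels = ch[3],
                 strides = c(8L, 16L, 32L)),
            class = "detector_config")
}

head_channels <- function(cfg) 4L + 1L + cfg$nc

#' Build a detector with deterministic initialization
#'
#' Two builds with the same seed produce bit-identical parameters.  The
#' parameter count depends only on the channel plan, not on `input_size`
#' (the network is fully convolutional).
#'
#' @param cfg A [detector_config()].
#' @param seed Integer seed.
#' @return A `rootvoid_model`: list with `cfg`, `params`, `state`, `seed`.
#' @export
build_detector <- function(cfg = detector_config(), seed = 0L) {
  stopifnot(inherits(cfg, "detector_config"))
  ch <- cfg$channels; cn <- cfg$neck_channels; no <- head_channels(cfg)
  bb_params <- if (cfg$use_resconv) res_conv_params else function(ci, co) cbs_params(ci, co, 3L)
  params <- with_seed(seed, {
    p <- list(
      b1 = bb_params(cfg$in_channels, ch[1]),
      b2 = bb_params(ch[1], ch[2]),
      b3 = bb_params(ch[2], ch[3]),
      b4 = bb_params(ch[3], ch[4]),
      b5 = bb_params(ch[4], ch[5]),
      lat5 = cbs_params(ch[5], cn, 1L),
      lat4 = cbs_params(ch[4], cn, 1L),
      lat3 = cbs_params(ch[3], cn, 1L),
      fpn4 = cbs_params(2L * cn, cn, 3L),
      fpn3 = cbs_params(2L * cn, cn, 3L),
      pan4 = cbs_params(cn, cn, 3L),
      pan4m = cbs_params(2L * cn, cn, 3L),
      pan5 = cbs_params(cn, cn, 3L),
      pan5m = cbs_params(2L * cn, cn, 3L),
      c2f = c2fcs_params(cn, cn),
      h3 = conv_params(cn, no, 1L),
      h4 = conv_params(cn, no, 1L),
      h5 = conv_params(cn, no, 1L))
    # start objectness strongly negative: almost everything is background
    for (h in c("h3", "h4", "h5")) p[[h]]$b[5] <- -4
    p
  })
  state <- list(
    b1 = list(bn = bn_state(ch[1])), b2 = list(bn = bn_state(ch[2])),
    b3 = list(bn = bn_state(ch[3])), b4 = list(bn = bn_state(ch[4])),
    b5 = list(bn = bn_state(ch[5])),
    lat5 = bn_state(cn), lat4 = bn_state(cn), lat3 = bn_state(cn),
    fpn4 = bn_state(cn), fpn3 = bn_state(cn),
    pan4 = bn_state(cn), pan4m = bn_state(cn),
    pan5 = bn_state(cn), pan5m = bn_state(cn),
    c2f = c2fcs_state(params$c2f))
  structure(list(cfg = cfg, params = params, state = state, seed = as.integer(seed)),
            class = "rootvoid_model")
}

# Full forward pass.  Returns the three raw head outputs, the updated BN
# state, named activations (for feature-map export), and backprop caches.
forward_full <- function(model, x, train = FALSE, keep_cache = train) {
  cfg <- model$cfg; p <- model$params; s <- model$state
  x <- as_t4(x)
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    stop("input is ", d[1], " x ", d[2], " but the model expects ",
         cfg$input_size, " x ", cfg$input_size)
  }
  if (d[3] != cfg$in_channels) {
    stop("input has ", d[3], " channels, model expects ", cfg$in_channels)
  }
  bb_fwd <- if (cfg$use_resconv) res_fwd else function(x, p, s, stride, train) {
    r <- cbs_fwd(x, p, s$bn, stride, train)
    list(y = r$y, s = list(bn = r$state), cache = r$cache)
  }
  r1 <- bb_fwd(x, p$b1, s$b1, 2L, train)
  r2 <- bb_fwd(r1$y, p$b2, s$b2, 2L, train)
  r3 <- bb_fwd(r2$y, p$b3, s$b3, 2L, train)
  r4 <- bb_fwd(r3$y, p$b4, s$b4, 2L, train)
  r5 <- bb_fwd(r4$y, p$b5, s$b5, 2L, train)
  l5 <- cbs_fwd(r5$y, p$lat5, s$lat5, 1L, train)
  u5 <- upsample2_fwd(l5$y)
  l4 <- cbs_fwd(r4$y, p$lat4, s$lat4, 1L, train)
  cat4 <- concat_ch(u5$y, l4$y)
  f4 <- cbs_fwd(cat4$y, p$fpn4, s$fpn4, 1L, train)
  u4 <- upsample2_fwd(f4$y)
  l3 <- cbs_fwd(r3$y, p$lat3, s$lat3, 1L, train)
  cat3 <- concat_ch(u4$y, l3$y)
  f3 <- cbs_fwd(cat3$y, p$fpn3, s$fpn3, 1L, train)
  d3 <- cbs_fwd(f3$y, p$pan4, s$pan4, 2L, train)
  cat44 <- concat_ch(d3$y, f4$y)
  m4 <- cbs_fwd(cat44$y, p$pan4m, s$pan4m, 1L, train)
  d4 <- cbs_fwd(m4$y, p$pan5, s$pan5, 2L, train)
  cat55 <- concat_ch(d4$y, l5$y)
  m5 <- cbs_fwd(cat55$y, p$pan5m, s$pan5m, 1L, train)
  c2 <- c2fcs_fwd(f3$y, p$c2f, s$c2f, cfg$S, cfg$heads, train,
                  use_att = cfg$use_tokatt)
  h3 <- conv_fwd(c2$y, p$h3, 1L, c(0L, 0L))
  h4 <- conv_fwd(m4$y, p$h4, 1L, c(0L, 0L))
  h5 <- conv_fwd(m5$y, p$h5, 1L, c(0L, 0L))
  state <- s
  state$b1 <- r1$s; state$b2 <- r2$s; state$b3 <- r3$s; state$b4 <- r4$s
  state$b5 <- r5$s
  state$lat5 <- l5$state; state$lat4 <- l4$state; state$lat3 <- l3$state
  state$fpn4 <- f4$state; state$fpn3 <- f3$state
  state$pan4 <- d3$state; state$pan4m <- m4$state
  state$pan5 <- d4$state; state$pan5m <- m5$state
  state$c2f <- c2$s
  acts <- list("backbone.stage1" = r1$y, "backbone.stage2" = r2$y,
               "backbone.stage3" = r3$y, "backbone.stage4" = r4$y,
               "backbone.stage5" = r5$y,
               "neck.p5" = l5$y, "neck.n4" = f4$y, "neck.n3" = f3$y,
               "neck.m4" = m4$y, "neck.m5" = m5$y,
               "head.small_in" = c2$y)
  cache <- NULL
  if (keep_cache) {
    cache <- list(r1 = r1$cache, r2 = r2$cache, r3 = r3$cache, r4 = r4$cache,
                  r5 = r5$cache, l5 = l5$cache, u5 = u5$cache, l4 = l4$cache,
                  cat4 = cat4$cache, f4 = f4$cache, u4 = u4$cache, l3 = l3$cache,
                  cat3 = cat3$cache, f3 = f3$cache, d3 = d3$cache,
                  cat44 = cat44$cache, m4 = m4$cache, d4 = d4$cache,
                  cat55 = cat55$cache, m5 = m5$cache, c2 = c2$cache,
                  h3 = h3$cache, h4 = h4$cache, h5 = h5$cache)
  }
  list(p3 = h3$y, p4 = h4$y, p5 = h5$y, state = state, acts = acts, cache = cache)
}

backward_full <- function(dp3, dp4, dp5, cache, use_resconv = TRUE) {
  bb_bwd <- if (use_resconv) res_bwd else function(dy, cache, need_input_grad = TRUE) {
    cbs_bwd(dy, cache)
  }
  h3b <- conv_bwd(dp3, cache$h3)
  h4b <- conv_bwd(dp4, cache$h4)
  h5b <- conv_bwd(dp5, cache$h5)
  c2b <- c2fcs_bwd(h3b$dx, cache$c2)
  m5b <- cbs_bwd(h5b$dx, cache$m5)
  sp55 <- split_ch(m5b$dx, cache$cat55)
  d4b <- cbs_bwd(sp55$da, cache$d4)
  m4b <- cbs_bwd(h4b$dx + d4b$dx, cache$m4)
  sp44 <- split_ch(m4b$dx, cache$cat44)
  d3b <- cbs_bwd(sp44$da, cache$d3)
  f3b <- cbs_bwd(c2b$dx + d3b$dx, cache$f3)
  sp3 <- split_ch(f3b$dx, cache$cat3)
  u4b <- upsample2_bwd(sp3$da, cache$u4)
  l3b <- cbs_bwd(sp3$db, cache$l3)
  f4b <- cbs_bwd(sp44$db + u4b$dx, cache$f4)
  sp4 <- split_ch(f4b$dx, cache$cat4)
  u5b <- upsample2_bwd(sp4$da, cache$u5)
  l4b <- cbs_bwd(sp4$db, cache$l4)
  l5b <- cbs_bwd(sp55$db + u5b$dx, cache$l5)
  r5b <- bb_bwd(l5b$dx, cache$r5)
  r4b <- bb_bwd(r5b$dx + l4b$dx, cache$r4)
  r3b <- bb_bwd(r4b$dx + l3b$dx, cache$r3)
  r2b <- bb_bwd(r3b$dx, cache$r2)
  r1b <- bb_bwd(r2b$dx, cache$r1, need_input_grad = FALSE)
  list(b1 = r1b$grads, b2 = r2b$grads, b3 = r3b$grads, b4 = r4b$grads,
       b5 = r5b$grads,
       lat5 = l5b$grads, lat4 = l4b$grads, lat3 = l3b$grads,
       fpn4 = f4b$grads, fpn3 = f3b$grads,
       pan4 = d3b$grads, pan4m = m4b$grads,
       pan5 = d4b$grads, pan5m = m5b$grads,
       c2f = c2b$grads,
       h3 = h3b$grads, h4 = h4b$grads, h5 = h5b$grads)
}

#' Run the detector forward
#'
#' @param model A `rootvoid_model`.
#' @param images A single `H x W` matrix / `H x W x C` array, or a batched
#'   `H x W x C x N` array, matching the configured input size.
#' @return List of three raw prediction arrays `p3`, `p4`, `p5` (grid x grid
#'   x (4 + 1 + nc) x N) at strides 8, 16, 32.
#' @export
detector_forward <- function(model, images) {
  if (is.matrix(images)) images <- array(images, dim = c(dim(images), 1L))
  out <- forward_full(model, images, train = FALSE, keep_cache = FALSE)
  out[c("p3", "p4", "p5")]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Decode raw head outputs into detections
#'
#' Anchor-free center + offset decoding: a cell `(r, c)` at stride `s`
#' predicts a center `((c - 1 + 2*sigmoid(tx) - 0.5) * s,
#' (r - 1 + 2*sigmoid(ty) - 0.5) * s)` and a size `exp(tw) * s` by
#' `exp(th) * s`; the score is `sigmoid(obj) * max(sigmoid(cls))`.
#' Detections below `cfg$conf_thresh` are dropped and boxes are clipped to
#' the image frame.
#'
#' @param raw List `p3`, `p4`, `p5` from [detector_forward()].
#' @param cfg The matching [detector_config()].
#' @param conf_thresh Optional override of the confidence threshold.
#' @return A list (one element per image) of detection data frames with
#'   columns `class`, `score`, `x1`, `y1`, `x2`, `y2`.
#' @export
decode_predictions <- function(raw, cfg, conf_thresh = NULL) {
  conf <- conf_thresh %||% cfg$conf_thresh
  sz <- cfg$input_size
  N <- dim(raw$p3)[4]
  out <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- list()
    for (si in 1:3) {
      a <- raw[[c("p3", "p4", "p5")[si]]]
      s <- cfg$strides[si]
      g <- dim(a)[1]
      tx <- a[, , 1, n]; ty <- a[, , 2, n]
      tw <- pmin(a[, , 3, n], 8); th <- pmin(a[, , 4, n], 8)
      obj <- sigmoid(a[, , 5, n])
      cls <- array(sigmoid(a[, , 5 + seq_len(cfg$nc), n, drop = FALSE]),
                   dim = c(g, g, cfg$nc))
      if (cfg$nc == 1L) {
        best_c <- matrix(1L, g, g); best_p <- cls[, , 1]
      } else {
        best_c <- apply(cls, c(1, 2), which.max)
        best_p <- apply(cls, c(1, 2), max)
      }
      score <- obj * best_p
      keep <- which(score >= conf, arr.ind = TRUE)
      if (nrow(keep)) {
        r <- keep[, 1]; cc <- keep[, 2]
        ii <- cbind(r, cc)
        cx <- (cc - 1 + 2 * sigmoid(tx[ii]) - 0.5) * s
        cy <- (r - 1 + 2 * sigmoid(ty[ii]) - 0.5) * s
        wpx <- exp(tw[ii]) * s; hpx <- exp(th[ii]) * s
        rows[[si]] <- data.frame(
          class = best_c[ii] - 1L, score = score[ii],
          x1 = pmin(pmax(cx - wpx / 2, 0), sz), y1 = pmin(pmax(cy - hpx / 2, 0), sz),
          x2 = pmin(pmax(cx + wpx / 2, 0), sz), y2 = pmin(pmax(cy + hpx / 2, 0), sz))
      }
    }
    d <- if (length(rows)) do.call(rbind, rows) else
      data.frame(class = integer(), score = numeric(), x1 = numeric(),
                 y1 = numeric(), x2 = numeric(), y2 = numeric())
    d <- d[order(-d$score), , drop = FALSE]
    if (nrow(d) > 300L) d <- d[seq_len(300L), , drop = FALSE]
    rownames(d) <- NULL
    out[[n]] <- d
  }
  out
}

#' Greedy non-maximum suppression
#'
#' Detections are sorted by descending score (ties keep insertion order);
#' a detection is kept iff its IoU with every kept same-class detection is
#' below `iou_thresh`.
#'
#' @param dets Detection data frame (`class`, `score`, `x1`, `y1`, `x2`, `y2`).
#' @param iou_thresh IoU threshold in (0, 1].
#' @return The surviving detections, in descending score order.
#' @export
nms <- function(dets, iou_thresh = 0.45) {
  stopifnot(iou_thresh > 0, iou_thresh <= 1)
  if (nrow(dets) == 0L) return(dets)
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  boxes <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  keep <- logical(nrow(dets))
  for (i in seq_len(nrow(dets))) {
    prev <- which(keep & dets$class == dets$class[i])
    if (!length(prev) ||
        all(box_iou(boxes[i, , drop = FALSE], boxes[prev, , drop = FALSE]) < iou_thresh)) {
      keep[i] <- TRUE
    }
  }
  out <- dets[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export intermediate feature maps
#'
#' Runs the model on one image and writes, for each requested stage, a
#' channel-mean heat map as PNG, the same matrix as TSV, and the full
#' activation array as RDS.  Deterministic for a fixed model and input.
#'
#' @param model A `rootvoid_model`.
#' @param image `H x W` matrix (or `labeled_image`).
#' @param stages Character vector of stage names (see Details); unknown
#'   names are rejected with the list of valid names.
#' @param out_dir Output directory.
#' @return Named list of the exported activation arrays, invisibly.
#' @details Valid stages: `backbone.stage1` ... `backbone.stage5`,
#'   `neck.p5`, `neck.n4`, `neck.n3`, `neck.m4`, `neck.m5`, `head.small_in`.
#' @export
export_feature_maps <- function(model, image, stages = c("backbone.stage3"),
                                out_dir = ".") {
  if (inherits(image, "labeled_image")) image <- image$image
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L, 1L))
  out <- forward_full(model, image, train = FALSE, keep_cache = FALSE)
  bad <- setdiff(stages, names(out$acts))
  if (length(bad)) {
    stop("unknown stage(s) ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(names(out$acts), collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (st in stages) {
    a <- out$acts[[st]][, , , 1, drop = FALSE]
    hm <- apply(a[, , , 1, drop = TRUE], c(1, 2), mean)
    rng <- range(hm)
    hmn <- if (diff(rng) > 0) (hm - rng[1]) / diff(rng) else hm * 0
    base <- file.path(out_dir, gsub("[^A-Za-z0-9_.]", "_", st))
    png::writePNG(hmn, paste0(base, ".png"))
    utils::write.table(hm, paste0(base, ".tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    saveRDS(a, paste0(base, ".rds"))
    res[[st]] <- a
  }
  invisible(res)
}

#' @export
print.rootvoid_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat("rootvoid detector: input ", x$cfg$input_size, "x", x$cfg$input_size,
      ", channels [", paste(x$cfg$channels, collapse = ", "), "], S = ",
      x$cfg$S, ", ", format(np, big.mark = ","), " parameters (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}
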