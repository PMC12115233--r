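# S3 methods for the fitted detector and labeled images.

#' @export
print.rootvoid_detector <- function(x, ...) {
  rl <- x$runlog
  cat("rootvoid detector fit\n")
  cat("  input: ", x$cfg$input_size, "x", x$cfg$input_size,
      "  channels [", paste(x$cfg$channels, collapse = ", "), "]\n", sep = "")
  cat("  epochs:", nrow(rl), " box loss:", x$train_cfg$loss,
      " lr:", x$train_cfg$lr, "\n")
  cat(sprintf("  final train loss %.4f", rl$loss[nrow(rl)]))
  last_map <- rev(rl$val_map50[!is.na(rl$val_map50)])
  if (length(last_map)) cat(sprintf("  val mAP50 %.4f", last_map[1]))
  cat("\n")
  invisible(x)
}

#' @export
summary.rootvoid_detector <- function(object, ...) {
  rl <- object$runlog
  cat("Training run summary\n")
  cat("--------------------\n")
  print.rootvoid_detector(object)
  cat("\nloss trajectory (first, min, last):",
      sprintf("%.4f / %.4f / %.4f", rl$loss[1], min(rl$loss), rl$loss[nrow(rl)]), "\n")
  ev <- rl[!is.na(rl$val_map50), c("epoch", "val_map50", "val_map50_95",
                                   "val_precision", "val_recall")]
  if (nrow(ev)) {
    cat("\nvalidation metrics:\n")
    print(utils::tail(ev, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Detect voids in an image
#'
#' @param object A `rootvoid_detector` fit.
#' @param image An image: `H x W` matrix in `[0, 1]`, a `labeled_image`,
#'   or a PNG file path.  Non-square or differently sized images are
#'   letterboxed to the model resolution and the detections mapped back.
#' @param conf_thresh Confidence threshold (default: the model config's).
#' @param use_best Use the best-mAP50 checkpoint rather than the last.
#' @param ... Unused.
#' @return Detection data frame (`class`, `score`, `x1`, `y1`, `x2`, `y2`)
#'   in the coordinates of the input image.
#' @export
predict.rootvoid_detector <- function(object, image, conf_thresh = NULL,
                                      use_best = TRUE, ...) {
  model <- if (use_best) object$best_model else object$model
  detect_voids(model, image, conf_thresh = conf_thresh)
}

#' Run detection with a raw model
#'
#' @param model A `rootvoid_model` (or `rootvoid_detector`).
#' @param image Image as in [predict.rootvoid_detector()].
#' @param conf_thresh Optional confidence threshold override.
#' @return Detection data frame in input-image pixel coordinates.
#' @export
detect_voids <- function(model, image, conf_thresh = NULL) {
  if (inherits(model, "rootvoid_detector")) model <- model$best_model
  if (is.character(image)) {
    img <- png::readPNG(image)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    image <- structure(list(image = img,
                            annotations = data.frame(class = integer(),
                                                     cx = numeric(), cy = numeric(),
                                                     w = numeric(), h = numeric()),
                            id = basename(image)),
                       class = "labeled_image")
  }
  if (is.matrix(image)) {
    image <- structure(list(image = image,
                            annotations = data.frame(class = integer(),
                                                     cx = numeric(), cy = numeric(),
                                                     w = numeric(), h = numeric()),
                            id = "image"),
                       class = "labeled_image")
  }
  sz <- model$cfg$input_size
  lb <- NULL
  if (nrow(image$image) != sz || ncol(image$image) != sz) {
    image <- letterbox_resize(image, sz)
    lb <- attr(image, "letterbox")
  }
  raw <- detector_forward(model, image$image)
  d <- decode_predictions(raw, model$cfg, conf_thresh = conf_thresh)[[1]]
  d <- nms(d, model$cfg$nms_iou)
  if (!is.null(lb) && nrow(d)) {
    b <- letterbox_invert(as.matrix(d[, c("x1", "y1", "x2", "y2")]), lb)
    d[, c("x1", "y1", "x2", "y2")] <- b
  }
  d
}

#' Burn detection boxes into an image matrix
#'
#' Draws 1-px bright rectangle outlines; useful for writing annotated PNGs
#' without a graphics device.
#'
#' @param img `H x W` matrix in `[0, 1]`.
#' @param boxes n x 4 matrix of pixel boxes.
#' @param value Outline intensity (default 1).
#' @return The annotated matrix.
#' @export
draw_boxes <- function(img, boxes, value = 1) {
  if (is.null(nrow(boxes)) || nrow(boxes) == 0L) return(img)
  H <- nrow(img); W <- ncol(img)
  for (i in seq_len(nrow(boxes))) {
    x1 <- max(1L, round(boxes[i, 1])); y1 <- max(1L, round(boxes[i, 2]))
    x2 <- min(W, round(boxes[i, 3])); y2 <- min(H, round(boxes[i, 4]))
    if (x2 < x1 || y2 < y1) next
    img[y1, x1:x2] <- value; img[y2, x1:x2] <- value
    img[y1:y2, x1] <- value; img[y1:y2, x2] <- value
  }
  img
}

#' @export
print.labeled_image <- function(x, ...) {
  cat("labeled_image '", x$id, "': ", nrow(x$image), "x", ncol(x$image),
      ", ", nrow(x$annotations), " annotation(s)\n", sep = "")
  invisible(x)
}

#' Plot a labeled image with its boxes
#'
#' @param x A `labeled_image`.
#' @param boxes Optional extra boxes (n x 4 px) drawn in a second style.
#' @param ... Passed to [graphics::rasterImage()]'s plot setup.
#' @export
plot.labeled_image <- function(x, boxes = NULL, ...) {
  img <- x$image
  gt <- ann_to_boxes(x$annotations, nrow(img), ncol(img))
  img <- draw_boxes(img, gt, value = 1)
  if (!is.null(boxes)) img <- draw_boxes(img, boxes, value = 0)
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
  graphics::rasterImage(img, 0, 0, 1, 1)
  graphics::title(x$id)
  invisible(x)
}

#' Plot the training run log
#'
#' Loss components and validation mAP50 against epoch.
#'
#' @param x A `rootvoid_detector`.
#' @param ... Unused.
#' @export
plot.rootvoid_detector <- function(x, ...) {
  rl <- x$runlog
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(rl$epoch, rl$loss, type = "l", xlab = "epoch", ylab = "train loss",
                 main = "loss")
  ev <- rl[!is.na(rl$val_map50), ]
  if (nrow(ev)) {
    graphics::plot(ev$epoch, ev$val_map50, type = "b", ylim = c(0, 1),
                   xlab = "epoch", ylab = "val mAP50", main = "validation")
  } else {
    graphics::plot.new()
  }
  invisible(x)
}

#' @export
coef.rootvoid_detector <- function(object, ...) object$model$params
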