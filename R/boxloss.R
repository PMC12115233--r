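# Bounding-box geometry and the IoU-family regression losses.
#
# Boxes are axis-aligned, in continuous pixel corner coordinates
# (x1, y1, x2, y2), origin top-left, y growing downward.  All operations are
# vectorized: a box argument is either a length-4 numeric vector or an n x 4
# matrix (one box per row); the two arguments are recycled to equal length.

as_box_matrix <- function(x, arg = "box") {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x1", "y1", "x2", "y2")])
  if (is.null(dim(x))) {
    if (length(x) != 4L) stop(arg, " must have 4 coordinates (x1, y1, x2, y2)")
    x <- matrix(x, 1L, 4L)
  }
  if (ncol(x) != 4L) stop(arg, " must be an n x 4 matrix")
  if (any(!is.finite(x))) stop(arg, " contains non-finite coordinates")
  bad <- which(x[, 3] < x[, 1] | x[, 4] < x[, 2])
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: need x1 <= x2 and y1 <= y2, got (%g, %g, %g, %g)",
                 arg, bad[1], x[bad[1], 1], x[bad[1], 2], x[bad[1], 3], x[bad[1], 4]))
  }
  colnames(x) <- c("x1", "y1", "x2", "y2")
  x
}

recycle_boxes <- function(a, b) {
  if (nrow(a) == nrow(b)) return(list(a = a, b = b))
  if (nrow(a) == 1L) return(list(a = a[rep(1L, nrow(b)), , drop = FALSE], b = b))
  if (nrow(b) == 1L) return(list(a = a, b = b[rep(1L, nrow(a)), , drop = FALSE]))
  stop("box arguments have incompatible lengths: ", nrow(a), " vs ", nrow(b))
}

#' Image frame for corner-distance normalization
#'
#' The corner-distance penalty of the combined loss is normalized by
#' `H^2 + W^2`, where `H` and `W` are the height and width of the *image*
#' (not of the boxes).  The default matches the 640 x 640 training
#' resolution of the detector.
#'
#' @param h,w Image height and width in pixels (positive).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(h = 640, w = 640) {
  if (!is.numeric(h) || !is.numeric(w) || length(h) != 1L || length(w) != 1L ||
      !is.finite(h) || !is.finite(w) || h <= 0 || w <= 0) {
    stop("image frame needs positive finite height and width, got H=", h, " W=", w)
  }
  structure(list(h = as.numeric(h), w = as.numeric(w)), class = "image_frame")
}

as_frame <- function(frame) {
  if (inherits(frame, "image_frame")) return(frame)
  if (is.numeric(frame) && length(frame) == 2L) return(image_frame(frame[1], frame[2]))
  stop("frame must be image_frame(h, w) or a numeric (h, w) pair")
}

#' Intersection over union of axis-aligned boxes
#'
#' Pairwise (row-by-row) IoU of two sets of boxes.  Disjoint boxes score 0;
#' the degenerate 0/0 case (both boxes of zero area) is defined as 0.
#'
#' @param a,b Boxes: length-4 vectors `(x1, y1, x2, y2)` or n x 4 matrices.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15))  # 25/175
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a, "a"); b <- as_box_matrix(b, "b")
  r <- recycle_boxes(a, b); a <- r$a; b <- r$b
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  u <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  unname(ifelse(u > 0, inter / u, 0))
}

# Shared term evaluation for the CIoU / CMIoU breakdowns.
# Aspect-ratio widths/heights are clamped to >= 1e-7 px so that zero-size
# predictions keep a finite, differentiable arctan ratio.
box_terms <- function(pred, gt) {
  iou <- box_iou(pred, gt)
  cxp <- (pred[, 1] + pred[, 3]) / 2; cyp <- (pred[, 2] + pred[, 4]) / 2
  cxg <- (gt[, 1] + gt[, 3]) / 2;     cyg <- (gt[, 2] + gt[, 4]) / 2
  rho2 <- (cxp - cxg)^2 + (cyp - cyg)^2
  cw <- pmax(pred[, 3], gt[, 3]) - pmin(pred[, 1], gt[, 1])
  ch <- pmax(pred[, 4], gt[, 4]) - pmin(pred[, 2], gt[, 2])
  c2 <- cw^2 + ch^2
  wp <- pmax(pred[, 3] - pred[, 1], 1e-7); hp <- pmax(pred[, 4] - pred[, 2], 1e-7)
  wg <- pmax(gt[, 3] - gt[, 1], 1e-7);     hg <- pmax(gt[, 4] - gt[, 2], 1e-7)
  q <- atan(wg / hg) - atan(wp / hp)
  v <- (4 / pi^2) * q^2
  denom <- (1 - iou) + v
  alpha <- ifelse(denom > 0, v / denom, 0)
  d1sq <- (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2
  d2sq <- (pred[, 3] - gt[, 3])^2 + (pred[, 4] - gt[, 4])^2
  list(iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = alpha, q = q,
       wp = wp, hp = hp, d1sq = d1sq, d2sq = d2sq,
       center_term = ifelse(c2 > 0, rho2 / c2, 0))
}

check_gt_positive <- function(gt) {
  bad <- which(gt[, 3] <= gt[, 1] | gt[, 4] <= gt[, 2])
  if (length(bad)) {
    stop("degenerate ground-truth box at row ", bad[1],
         ": width and height must be positive")
  }
}

breakdown_df <- function(t, mpd_penalty, total) {
  df <- data.frame(iou = t$iou, rho2 = unname(t$rho2), c2 = unname(t$c2),
                   v = unname(t$v), alpha = unname(t$alpha),
                   d1sq = unname(t$d1sq), d2sq = unname(t$d2sq),
                   mpd_penalty = unname(mpd_penalty), total = unname(total))
  rownames(df) <- NULL
  structure(df, class = c("loss_breakdown", "data.frame"))
}

#' Complete-IoU (CIoU) regression loss
#'
#' `1 - IoU + rho^2/c^2 + alpha * v`, where `rho^2` is the squared distance
#' between box centers, `c^2` the squared diagonal of the smallest enclosing
#' box, `v = (4/pi^2) (arctan(w_gt/h_gt) - arctan(w/h))^2` the aspect-ratio
#' penalty, and `alpha = v / ((1 - IoU) + v)` its weight.
#'
#' @param pred,gt Predicted and ground-truth boxes (vector or n x 4 matrix);
#'   ground-truth boxes must have positive width and height.
#' @return A `loss_breakdown` data frame with one row per pair: columns
#'   `iou`, `rho2`, `c2`, `v`, `alpha`, `d1sq`, `d2sq`, `mpd_penalty`
#'   (`NA` here, populated by [cmiou_loss()]) and `total`.
#' @export
ciou_loss <- function(pred, gt) {
  pred <- as_box_matrix(pred, "pred"); gt <- as_box_matrix(gt, "gt")
  r <- recycle_boxes(pred, gt); pred <- r$a; gt <- r$b
  check_gt_positive(gt)
  t <- box_terms(pred, gt)
  breakdown_df(t, NA_real_, 1 - t$iou + t$center_term + t$alpha * t$v)
}

#' Squared corner distances between two boxes
#'
#' `d1^2` is the squared Euclidean distance between top-left corners,
#' `d2^2` between bottom-right corners.
#'
#' @inheritParams ciou_loss
#' @return A two-column matrix `(d1sq, d2sq)`.
#' @export
mpdiou_terms <- function(pred, gt) {
  pred <- as_box_matrix(pred, "pred"); gt <- as_box_matrix(gt, "gt")
  r <- recycle_boxes(pred, gt); pred <- r$a; gt <- r$b
  cbind(d1sq = (pred[, 1] - gt[, 1])^2 + (pred[, 2] - gt[, 2])^2,
        d2sq = (pred[, 3] - gt[, 3])^2 + (pred[, 4] - gt[, 4])^2)
}

#' Minimum-point-distance IoU similarity
#'
#' `IoU - (d1^2 + d2^2) / (H^2 + W^2)`.  Note the sign: this is a similarity
#' (1 for identical boxes, possibly negative for distant ones), implemented
#' verbatim; the trainable objective is [cmiou_loss()].
#'
#' @inheritParams ciou_loss
#' @param frame An [image_frame()] (or `c(h, w)`) supplying the normalizer.
#' @return Numeric vector of similarity scores.
#' @export
mpdiou <- function(pred, gt, frame = image_frame()) {
  frame <- as_frame(frame)
  d <- mpdiou_terms(pred, gt)
  box_iou(pred, gt) - (d[, 1] + d[, 2]) / (frame$h^2 + frame$w^2)
}

#' Combined MPD/Complete IoU (CMIoU) regression loss
#'
#' The full bounding-box objective:
#' `1 - IoU + (d1^2 + d2^2)/(H^2 + W^2) + rho^2/c^2 + alpha * v`.
#' Unlike `1 - IoU`, it has a non-zero gradient when the boxes are disjoint:
#' the corner- and center-distance penalties keep pulling the prediction
#' toward the target.
#'
#' @inheritParams mpdiou
#' @return A `loss_breakdown` data frame (see [ciou_loss()]); `total >= 0`
#'   with equality iff `pred == gt`.
#' @export
cmiou_loss <- function(pred, gt, frame = image_frame()) {
  frame <- as_frame(frame)
  pred <- as_box_matrix(pred, "pred"); gt <- as_box_matrix(gt, "gt")
  r <- recycle_boxes(pred, gt); pred <- r$a; gt <- r$b
  check_gt_positive(gt)
  t <- box_terms(pred, gt)
  mpd <- (t$d1sq + t$d2sq) / (frame$h^2 + frame$w^2)
  breakdown_df(t, mpd, 1 - t$iou + mpd + t$center_term + t$alpha * t$v)
}

#' Analytic gradient of the box regression loss
#'
#' Gradient of the CIoU or CMIoU total with respect to the four predicted
#' coordinates.  Following the CIoU convention, `alpha` is treated as a
#' constant during differentiation (its gradient is stopped); the IoU,
#' center, corner, and `v` terms are differentiated exactly.  At the
#' measure-zero ties of `max`/`min` a one-sided subgradient is used.
#'
#' @inheritParams mpdiou
#' @param loss `"cmiou"` (default) or `"ciou"` (omits the corner penalty).
#' @param exact_alpha Also differentiate `alpha` (default `FALSE`, the
#'   stop-gradient convention used in training; `TRUE` gives the exact
#'   derivative of the printed total, e.g. for finite-difference checks).
#' @return An n x 4 matrix `d total / d (x1, y1, x2, y2)`.
#' @export
box_loss_grad <- function(pred, gt, frame = image_frame(), loss = c("cmiou", "ciou"),
                          exact_alpha = FALSE) {
  loss <- match.arg(loss)
  frame <- as_frame(frame)
  pred <- as_box_matrix(pred, "pred"); gt <- as_box_matrix(gt, "gt")
  r <- recycle_boxes(pred, gt); pred <- r$a; gt <- r$b
  check_gt_positive(gt)
  t <- box_terms(pred, gt)
  x1 <- pred[, 1]; y1 <- pred[, 2]; x2 <- pred[, 3]; y2 <- pred[, 4]
  g1 <- gt[, 1]; g2 <- gt[, 2]; g3 <- gt[, 3]; g4 <- gt[, 4]
  wp <- x2 - x1; hp <- y2 - y1
  iw <- pmax(0, pmin(x2, g3) - pmax(x1, g1))
  ih <- pmax(0, pmin(y2, g4) - pmax(y1, g2))
  inter <- iw * ih
  Ap <- wp * hp; Ag <- (g3 - g1) * (g4 - g2)
  U <- Ap + Ag - inter
  ovl <- iw > 0 & ih > 0
  # dI/d(pred coords)
  dI <- cbind(ifelse(ovl & x1 > g1, -ih, 0), ifelse(ovl & y1 > g2, -iw, 0),
              ifelse(ovl & x2 < g3, ih, 0), ifelse(ovl & y2 < g4, iw, 0))
  dAp <- cbind(-hp, -wp, hp, wp)
  dIoU <- (dI * U - inter * (dAp - dI)) / pmax(U, 1e-12)^2
  # center term rho^2 / c^2
  cxd <- (x1 + x2 - g1 - g3) / 2; cyd <- (y1 + y2 - g2 - g4) / 2
  drho2 <- cbind(cxd, cyd, cxd, cyd)
  cw <- pmax(x2, g3) - pmin(x1, g1); ch <- pmax(y2, g4) - pmin(y1, g2)
  dc2 <- cbind(ifelse(x1 < g1, -2 * cw, 0), ifelse(y1 < g2, -2 * ch, 0),
               ifelse(x2 > g3, 2 * cw, 0), ifelse(y2 > g4, 2 * ch, 0))
  c2 <- pmax(t$c2, 1e-12)
  dcenter <- (drho2 * c2 - t$rho2 * dc2) / c2^2
  # aspect term alpha * v (alpha detached; clamp kills the gradient when active)
  wc <- t$wp; hc <- t$hp
  live_w <- as.numeric(wp > 1e-7); live_h <- as.numeric(hp > 1e-7)
  dv_dw <- -(8 * t$q / pi^2) * hc / (hc^2 + wc^2) * live_w
  dv_dh <- (8 * t$q / pi^2) * wc / (hc^2 + wc^2) * live_h
  dv <- cbind(-dv_dw, -dv_dh, dv_dw, dv_dh)
  dasp <- t$alpha * dv
  if (exact_alpha) {
    # alpha = v / D with D = (1 - IoU) + v; dalpha = (dv * D - v * (dv - dIoU)) / D^2
    D <- pmax((1 - t$iou) + t$v, 1e-12)
    dalpha <- (dv * D - t$v * (dv - dIoU)) / D^2
    dasp <- dasp + dalpha * t$v
  }
  grad <- -dIoU + dcenter + dasp
  if (loss == "cmiou") {
    nrm <- frame$h^2 + frame$w^2
    grad <- grad + cbind(2 * (x1 - g1), 2 * (y1 - g2),
                         2 * (x2 - g3), 2 * (y2 - g4)) / nrm
  }
  colnames(grad) <- c("x1", "y1", "x2", "y2")
  grad
}

#' Weighted sum of the three detector loss components
#'
#' `weights[1] * cls + weights[2] * box + weights[3] * obj`.  All terms must
#' be finite and non-negative; weights must be non-negative.
#'
#' @param cls_term,box_term,obj_term Scalar loss components.
#' @param weights Numeric triple of non-negative weights.
#' @return The scalar weighted sum.
#' @export
compose_total_loss <- function(cls_term, box_term, obj_term, weights = c(1, 1, 1)) {
  terms <- c(cls_term, box_term, obj_term)
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0)) {
    stop("weights must be three finite non-negative numbers")
  }
  if (any(!is.finite(terms)) || any(terms < 0)) {
    stop("loss terms must be finite and non-negative, got (",
         paste(signif(terms, 6), collapse = ", "), ")")
  }
  sum(weights * terms)
}
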