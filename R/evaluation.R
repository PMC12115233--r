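# From-scratch detection metrics: greedy TP/FP matching, precision/recall,
# 101-point interpolated average precision, mAP50 and mAP50-95.

as_det_df <- function(dets) {
  if (is.null(dets) || (is.data.frame(dets) && nrow(dets) == 0L)) {
    return(data.frame(image = character(), class = integer(), score = numeric(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric()))
  }
  stopifnot(is.data.frame(dets))
  need <- c("image", "class", "score", "x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(dets))
  if (length(miss)) stop("detections lack columns: ", paste(miss, collapse = ", "))
  dets[, need]
}

as_gt_df <- function(gts) {
  if (is.null(gts) || (is.data.frame(gts) && nrow(gts) == 0L)) {
    return(data.frame(image = character(), class = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric()))
  }
  stopifnot(is.data.frame(gts))
  need <- c("image", "class", "x1", "y1", "x2", "y2")
  miss <- setdiff(need, names(gts))
  if (length(miss)) stop("ground truth lacks columns: ", paste(miss, collapse = ", "))
  gts[, need]
}

#' Greedy matching of detections to ground truth
#'
#' Predictions are processed in descending score order (ties broken by
#' insertion order).  Each prediction matches the not-yet-matched
#' ground-truth box of the same image and class with the highest IoU,
#' provided that IoU is at least `iou_thresh`; it is then a true positive,
#' otherwise a false positive.  Each ground-truth box matches at most once;
#' unmatched ground truth are the false negatives.
#'
#' @param dets Data frame with columns `image`, `class`, `score`,
#'   `x1`, `y1`, `x2`, `y2`.
#' @param gts Data frame with columns `image`, `class`, `x1`, `y1`, `x2`, `y2`.
#' @param iou_thresh IoU threshold in (0, 1).
#' @return A `match_result`: data frame of predictions in processing order
#'   with logical column `tp`, plus attributes `n_gt` (total ground truth)
#'   and `matched_gt` (index of the matched GT row, NA for FP).
#' @export
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  stopifnot(iou_thresh > 0, iou_thresh < 1)
  dets <- as_det_df(dets); gts <- as_gt_df(gts)
  ord <- order(-dets$score)           # stable: ties keep insertion order
  dets <- dets[ord, , drop = FALSE]
  n <- nrow(dets)
  tp <- logical(n)
  matched_gt <- rep(NA_integer_, n)
  gt_taken <- logical(nrow(gts))
  if (n > 0 && nrow(gts) > 0) {
    gt_boxes <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(n)) {
      cand <- which(!gt_taken & gts$image == dets$image[i] & gts$class == dets$class[i])
      if (!length(cand)) next
      ious <- box_iou(matrix(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]), 1, 4),
                      gt_boxes[cand, , drop = FALSE])
      best <- which.max(ious)
      if (ious[best] >= iou_thresh) {
        tp[i] <- TRUE
        gt_taken[cand[best]] <- TRUE
        matched_gt[i] <- cand[best]
      }
    }
  }
  out <- cbind(dets, tp = tp)
  rownames(out) <- NULL
  structure(out, n_gt = nrow(gts), matched_gt = matched_gt,
            iou_thresh = iou_thresh, class = c("match_result", "data.frame"))
}

#' Cumulative precision-recall curve from a match result
#'
#' One point per prediction in score order: precision `cumTP/(cumTP+cumFP)`
#' and recall `cumTP/n_gt`.
#'
#' @param m A `match_result` from [match_detections()].
#' @return A `pr_curve` data frame with columns `recall`, `precision`,
#'   `score`; empty when there are no predictions.
#' @export
precision_recall <- function(m) {
  stopifnot(inherits(m, "match_result"))
  n_gt <- attr(m, "n_gt")
  if (nrow(m) == 0L) {
    return(structure(data.frame(recall = numeric(), precision = numeric(),
                                score = numeric()),
                     n_gt = n_gt, class = c("pr_curve", "data.frame")))
  }
  ctp <- cumsum(m$tp)
  cfp <- cumsum(!m$tp)
  if (n_gt == 0L) {
    warning("no ground-truth objects: recall reported as 0")
    recall <- rep(0, nrow(m))
  } else {
    recall <- ctp / n_gt
  }
  structure(data.frame(recall = recall, precision = ctp / (ctp + cfp), score = m$score),
            n_gt = n_gt, class = c("pr_curve", "data.frame"))
}

#' 101-point interpolated average precision
#'
#' The precision envelope is made non-increasing in recall, sampled at the
#' 101 recall levels 0.00, 0.01, ..., 1.00, and averaged (the convention
#' behind COCO-style mAP50-95 reporting).
#'
#' @param curve A `pr_curve` from [precision_recall()].
#' @return AP in `[0, 1]`; 0 for an empty curve.
#' @export
average_precision <- function(curve) {
  if (nrow(curve) == 0L) return(0)
  r <- curve$recall; p <- curve$precision
  # envelope: max precision among points with recall >= the sample level
  o <- order(r)
  r <- r[o]; p <- p[o]
  env <- rev(cummax(rev(p)))
  samples <- seq(0, 1, by = 0.01)
  idx <- findInterval(samples, r, left.open = TRUE) + 1L  # first point with recall >= s
  vals <- ifelse(idx <= length(r), env[pmin(idx, length(r))], 0)
  mean(vals)
}

#' mAP over IoU thresholds and classes
#'
#' Computes per-class AP at each IoU threshold 0.50, 0.55, ..., 0.95;
#' `mAP50` is the class mean at 0.5, `mAP50_95` the mean over all ten
#' thresholds then over classes.  The scalar `recall`/`precision` pair is
#' reported at the confidence threshold maximizing F1 at IoU 0.5.
#'
#' @param dets,gts As in [match_detections()].
#' @param iou_thresholds Vector of IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @return An `eval_report` list: `map50`, `map50_95`, `precision`, `recall`,
#'   `f1`, `conf_threshold`, `ap` (class x threshold matrix), `n_gt`, `valid`.
#' @export
map_over_thresholds <- function(dets, gts, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  dets <- as_det_df(dets); gts <- as_gt_df(gts)
  if (nrow(gts) == 0L) {
    warning("no ground truth at all: report flagged invalid")
    return(structure(list(map50 = NA_real_, map50_95 = NA_real_,
                          precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                          conf_threshold = NA_real_, ap = NULL, n_gt = 0L,
                          valid = FALSE),
                     class = "eval_report"))
  }
  classes <- sort(unique(gts$class))
  ap <- matrix(0, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", iou_thresholds)))
  for (ci in seq_along(classes)) {
    dsub <- dets[dets$class == classes[ci], , drop = FALSE]
    gsub <- gts[gts$class == classes[ci], , drop = FALSE]
    for (ti in seq_along(iou_thresholds)) {
      m <- match_detections(dsub, gsub, iou_thresholds[ti])
      ap[ci, ti] <- average_precision(precision_recall(m))
    }
  }
  i50 <- which.min(abs(iou_thresholds - 0.5))
  # operating point: confidence maximizing F1 at IoU 0.5, all classes jointly
  m50 <- match_detections(dets, gts, 0.5)
  if (nrow(m50) > 0L) {
    ctp <- cumsum(m50$tp); cfp <- cumsum(!m50$tp)
    prec <- ctp / (ctp + cfp); rec <- ctp / attr(m50, "n_gt")
    f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
    best <- which.max(f1)    # first (= highest threshold) among ties
    op <- c(prec[best], rec[best], f1[best], m50$score[best])
  } else {
    op <- c(0, 0, 0, NA_real_)
  }
  structure(list(map50 = mean(ap[, i50]),
                 map50_95 = mean(rowMeans(ap)),
                 precision = op[1], recall = op[2], f1 = op[3],
                 conf_threshold = op[4],
                 ap = ap, n_gt = nrow(gts), valid = TRUE),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  if (!x$valid) {
    cat("eval_report: INVALID (no ground truth)\n")
    return(invisible(x))
  }
  cat(sprintf("eval_report: mAP50 %.4f | mAP50-95 %.4f | P %.4f | R %.4f (conf %.3f, F1 %.4f)\n",
              x$map50, x$map50_95, x$precision, x$recall, x$conf_threshold, x$f1))
  invisible(x)
}

#' Read detections from a line-oriented text file
#'
#' Format: one `image_id class score x1 y1 x2 y2` line per detection.
#'
#' @param path File path.
#' @return Detection data frame as used by [match_detections()].
#' @export
read_detections <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) return(as_det_df(NULL))
  d <- utils::read.table(path, col.names = c("image", "class", "score",
                                             "x1", "y1", "x2", "y2"),
                         colClasses = c("character", "integer", rep("numeric", 5)))
  d
}

#' Write detections to the line-oriented text format
#'
#' @param dets Detection data frame.
#' @param path File path.
#' @export
write_detections <- function(dets, path) {
  dets <- as_det_df(dets)
  lines <- sprintf("%s %d %.6f %.2f %.2f %.2f %.2f", dets$image, dets$class,
                   dets$score, dets$x1, dets$y1, dets$x2, dets$y2)
  writeLines(lines, path)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$ap)) {
    x$ap <- as.data.frame(x$ap)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
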