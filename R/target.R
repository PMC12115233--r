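# Ground-truth assignment and the composite detection loss.
#
# One-to-many assignment: every ground-truth box goes to one scale by area
# (<= 32^2 px -> stride 8, <= 96^2 -> stride 16, else stride 32), to its
# containing cell plus the two nearest neighbour cells (the adjacent cell
# in x and in y toward the box center).  The box term is the CMIoU (or
# CIoU) loss on the decoded boxes at assigned cells; classification and
# objectness are binary cross-entropies on logits, the objectness balanced
# between positive and negative cells.

bce_logits <- function(z, t) pmax(z, 0) - z * t + log1p(exp(-abs(z)))

scale_for_area <- function(area) ifelse(area <= 32^2, 1L, ifelse(area <= 96^2, 2L, 3L))

# Build the assignment table: one row per (gt, cell) pair.
assign_targets <- function(gt_boxes, gt_class, image_idx, cfg) {
  sz <- cfg$input_size
  rows <- list()
  if (length(image_idx)) {
    for (i in seq_along(image_idx)) {
      b <- unname(gt_boxes[i, ])
      w <- b[3] - b[1]; h <- b[4] - b[2]
      si <- scale_for_area(w * h)
      s <- cfg$strides[si]; g <- sz %/% s
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      col0 <- min(max(floor(cx / s) + 1, 1), g)
      row0 <- min(max(floor(cy / s) + 1, 1), g)
      fx <- cx / s - (col0 - 1)   # offset within cell, [0, 1)
      fy <- cy / s - (row0 - 1)
      coln <- col0 + if (fx < 0.5) -1L else 1L
      rown <- row0 + if (fy < 0.5) -1L else 1L
      cells <- rbind(c(row0, col0),
                     if (coln >= 1 && coln <= g) c(row0, coln),
                     if (rown >= 1 && rown <= g) c(rown, col0))
      rows[[length(rows) + 1L]] <-
        data.frame(img = image_idx[i], scale = si, row = cells[, 1],
                   col = cells[, 2], gt = i, class = gt_class[i],
                   cx = cx, cy = cy,
                   x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4])
    }
  }
  if (!length(rows)) {
    return(data.frame(img = integer(), scale = integer(), row = integer(),
                      col = integer(), gt = integer(), class = integer(),
                      cx = numeric(), cy = numeric(), x1 = numeric(),
                      y1 = numeric(), x2 = numeric(), y2 = numeric()))
  }
  a <- do.call(rbind, rows)
  # a cell serves at most one ground truth: first (insertion order) wins
  key <- paste(a$img, a$scale, a$row, a$col)
  a[!duplicated(key), , drop = FALSE]
}

# Composite loss and its gradient with respect to the raw head outputs.
# `targets` is a list of per-image lists: list(boxes = n x 4 px, class = int).
detection_loss <- function(raw, targets, cfg, loss = "cmiou",
                           weights = c(cls = 0.5, box = 5, obj = 1)) {
  sz <- cfg$input_size
  N <- dim(raw$p3)[4]
  gt_boxes <- NULL; gt_class <- integer(); image_idx <- integer()
  for (n in seq_len(N)) {
    tb <- targets[[n]]
    if (!is.null(tb) && nrow(tb$boxes) > 0L) {
      gt_boxes <- rbind(gt_boxes, tb$boxes)
      gt_class <- c(gt_class, tb$class)
      image_idx <- c(image_idx, rep(n, nrow(tb$boxes)))
    }
  }
  asg <- assign_targets(gt_boxes, gt_class, image_idx, cfg)
  draw <- list(p3 = array(0, dim = dim(raw$p3)),
               p4 = array(0, dim = dim(raw$p4)),
               p5 = array(0, dim = dim(raw$p5)))
  npos_tot <- nrow(asg)
  # IoU-aware objectness target: each positive cell regresses its objectness
  # toward the IoU of its currently decoded box with the ground truth
  # (detached), so scores track localization quality and duplicates fade.
  obj_tgt_val <- numeric(npos_tot)
  if (npos_tot > 0) {
    for (si in 1:3) {
      rows_i <- which(asg$scale == si)
      if (!length(rows_i)) next
      sel <- asg[rows_i, , drop = FALSE]
      a <- raw[[c("p3", "p4", "p5")[si]]]
      s <- cfg$strides[si]
      tx <- a[cbind(sel$row, sel$col, 1L, sel$img)]
      ty <- a[cbind(sel$row, sel$col, 2L, sel$img)]
      tw <- pmin(a[cbind(sel$row, sel$col, 3L, sel$img)], 8)
      th <- pmin(a[cbind(sel$row, sel$col, 4L, sel$img)], 8)
      cx <- (sel$col - 1 + 2 * sigmoid(tx) - 0.5) * s
      cy <- (sel$row - 1 + 2 * sigmoid(ty) - 0.5) * s
      wp <- exp(tw) * s; hp <- exp(th) * s
      pred <- cbind(cx - wp / 2, cy - hp / 2, cx + wp / 2, cy + hp / 2)
      obj_tgt_val[rows_i] <- box_iou(pred, as.matrix(sel[, c("x1", "y1", "x2", "y2")]))
    }
  }
  # ---- objectness: balanced BCE over positive and negative cells ----------
  obj_loss <- 0
  for (si in 1:3) {
    nm <- c("p3", "p4", "p5")[si]
    a <- raw[[nm]]
    g <- dim(a)[1]
    z <- a[, , 5, , drop = FALSE]
    tgt <- array(0, dim = dim(z))
    sel_i <- which(asg$scale == si)
    sel <- asg[sel_i, , drop = FALSE]
    if (nrow(sel)) tgt[cbind(sel$row, sel$col, 1L, sel$img)] <- obj_tgt_val[sel_i]
    pos <- array(FALSE, dim = dim(z))
    if (nrow(sel)) pos[cbind(sel$row, sel$col, 1L, sel$img)] <- TRUE
    bce <- bce_logits(z, tgt)
    # negatives carry a focal factor p^2 (detached) and, like the positives,
    # are normalized by the positive count, so confident false positives on
    # background cells receive a strong corrective gradient
    pr <- sigmoid(z)
    focal <- ifelse(pos, 1, pr * pr)
    wmat <- focal / max(1, npos_tot)
    obj_loss <- obj_loss + sum(bce * wmat)
    dz <- (pr - tgt) * wmat
    draw[[nm]][, , 5, ] <- draw[[nm]][, , 5, ] + weights[["obj"]] * as.vector(dz)
  }
  # ---- classification and box terms at assigned cells ---------------------
  cls_loss <- 0; box_loss <- 0
  if (npos_tot > 0) {
    for (si in 1:3) {
      sel <- asg[asg$scale == si, , drop = FALSE]
      if (!nrow(sel)) next
      nm <- c("p3", "p4", "p5")[si]
      a <- raw[[nm]]
      s <- cfg$strides[si]
      # classification: one-hot over nc channels at the assigned cells
      for (ch in seq_len(cfg$nc)) {
        idx <- cbind(sel$row, sel$col, 5L + ch, sel$img)
        z <- a[idx]
        t <- as.numeric(sel$class == ch - 1L)
        cls_loss <- cls_loss + sum(bce_logits(z, t))
        draw[[nm]][idx] <- draw[[nm]][idx] +
          weights[["cls"]] * (sigmoid(z) - t) / (npos_tot * cfg$nc)
      }
      # box regression on decoded boxes
      i_tx <- cbind(sel$row, sel$col, 1L, sel$img)
      i_ty <- cbind(sel$row, sel$col, 2L, sel$img)
      i_tw <- cbind(sel$row, sel$col, 3L, sel$img)
      i_th <- cbind(sel$row, sel$col, 4L, sel$img)
      tx <- a[i_tx]; ty <- a[i_ty]; tw <- pmin(a[i_tw], 8); th <- pmin(a[i_th], 8)
      sx <- sigmoid(tx); sy <- sigmoid(ty)
      cx <- (sel$col - 1 + 2 * sx - 0.5) * s
      cy <- (sel$row - 1 + 2 * sy - 0.5) * s
      wp <- exp(tw) * s; hp <- exp(th) * s
      pred <- cbind(cx - wp / 2, cy - hp / 2, cx + wp / 2, cy + hp / 2)
      gtb <- as.matrix(sel[, c("x1", "y1", "x2", "y2")])
      bl <- if (loss == "cmiou") {
        cmiou_loss(pred, gtb, image_frame(sz, sz))
      } else {
        ciou_loss(pred, gtb)
      }
      box_loss <- box_loss + sum(bl$total)
      gb <- box_loss_grad(pred, gtb, image_frame(sz, sz), loss) / npos_tot
      dcx <- gb[, 1] + gb[, 3]; dcy <- gb[, 2] + gb[, 4]
      dwp <- (gb[, 3] - gb[, 1]) / 2; dhp <- (gb[, 4] - gb[, 2]) / 2
      wb <- weights[["box"]]
      draw[[nm]][i_tx] <- draw[[nm]][i_tx] + wb * dcx * 2 * sx * (1 - sx) * s
      draw[[nm]][i_ty] <- draw[[nm]][i_ty] + wb * dcy * 2 * sy * (1 - sy) * s
      draw[[nm]][i_tw] <- draw[[nm]][i_tw] + wb * dwp * wp * (a[i_tw] <= 8)
      draw[[nm]][i_th] <- draw[[nm]][i_th] + wb * dhp * hp * (a[i_th] <= 8)
    }
    cls_loss <- cls_loss / (npos_tot * cfg$nc)
    box_loss <- box_loss / npos_tot
  }
  total <- compose_total_loss(cls_loss, box_loss, obj_loss,
                              weights[c("cls", "box", "obj")])
  list(total = total, cls = cls_loss, box = box_loss, obj = obj_loss,
       n_pos = npos_tot, draw = draw)
}
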