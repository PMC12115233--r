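# Independent reference implementations used as oracles.  These are written
# as plain scalar code, deliberately sharing no internals with the package.

# IoU by rasterization: count sub-pixel cells whose centers fall in each box.
oracle_iou_grid <- function(a, b, res = 0.05) {
  x0 <- min(a[1], b[1]); x1 <- max(a[3], b[3])
  y0 <- min(a[2], b[2]); y1 <- max(a[4], b[4])
  xs <- seq(x0 + res / 2, x1, by = res)
  ys <- seq(y0 + res / 2, y1, by = res)
  ina <- outer(ys >= a[2] & ys <= a[4], xs >= a[1] & xs <= a[3], `&`)
  inb <- outer(ys >= b[2] & ys <= b[4], xs >= b[1] & xs <= b[3], `&`)
  inter <- sum(ina & inb)
  union <- sum(ina | inb)
  if (union == 0) 0 else inter / union
}

# Term-by-term scalar evaluation of the loss family.
oracle_terms <- function(pred, gt, H = 640, W = 640) {
  ix1 <- max(pred[1], gt[1]); iy1 <- max(pred[2], gt[2])
  ix2 <- min(pred[3], gt[3]); iy2 <- min(pred[4], gt[4])
  inter <- max(0, ix2 - ix1) * max(0, iy2 - iy1)
  ap <- (pred[3] - pred[1]) * (pred[4] - pred[2])
  ag <- (gt[3] - gt[1]) * (gt[4] - gt[2])
  u <- ap + ag - inter
  iou <- if (u > 0) inter / u else 0
  bx <- (pred[1] + pred[3]) / 2; by <- (pred[2] + pred[4]) / 2
  gx <- (gt[1] + gt[3]) / 2; gy <- (gt[2] + gt[4]) / 2
  rho2 <- (bx - gx)^2 + (by - gy)^2
  cw <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  ch <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  c2 <- cw^2 + ch^2
  w <- max(pred[3] - pred[1], 1e-7); h <- max(pred[4] - pred[2], 1e-7)
  wg <- max(gt[3] - gt[1], 1e-7); hg <- max(gt[4] - gt[2], 1e-7)
  v <- (4 / pi^2) * (atan(wg / hg) - atan(w / h))^2
  alpha <- if ((1 - iou) + v > 0) v / ((1 - iou) + v) else 0
  d1sq <- (pred[1] - gt[1])^2 + (pred[2] - gt[2])^2
  d2sq <- (pred[3] - gt[3])^2 + (pred[4] - gt[4])^2
  list(iou = iou, rho2 = rho2, c2 = c2, v = v, alpha = alpha,
       d1sq = d1sq, d2sq = d2sq,
       ciou = 1 - iou + rho2 / c2 + alpha * v,
       mpdiou = iou - (d1sq + d2sq) / (H^2 + W^2),
       cmiou = 1 - iou + (d1sq + d2sq) / (H^2 + W^2) + rho2 / c2 + alpha * v)
}

random_box <- function(lo = 0, hi = 100, minside = 1, maxside = 40) {
  x1 <- runif(1, lo, hi - minside); y1 <- runif(1, lo, hi - minside)
  c(x1, y1, x1 + runif(1, minside, maxside), y1 + runif(1, minside, maxside))
}

# Direct-arithmetic 2-D convolution (stride 1 or 2, zero padding).
oracle_conv <- function(x, w, b, stride = 1, pad = 1) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  k <- dim(w)[1]; Co <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, Co))
  for (co in 1:Co) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- b[co]
    for (ci in 1:Ci) for (ki in 1:k) for (kj in 1:k) {
      hi <- (ho - 1) * stride - pad + ki
      wi <- (wo - 1) * stride - pad + kj
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc <- acc + x[hi, wi, ci] * w[ki, kj, ci, co]
      }
    }
    y[ho, wo, co] <- acc
  }
  y
}

# Exhaustive greedy NMS (same rule, different structure).
oracle_nms <- function(dets, thr) {
  ord <- order(-dets$score)
  d <- dets[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j] || d$class[j] != d$class[i]) next
      iou <- oracle_pair_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                             as.numeric(d[j, c("x1", "y1", "x2", "y2")]))
      if (iou >= thr) keep[j] <- FALSE
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_pair_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (u > 0) inter / u else 0
}

# Independent evaluation pipeline: greedy matching, cumulative PR, and AP by
# dense sampling of the non-increasing precision envelope.
oracle_match <- function(dets, gts, thr) {
  ord <- order(-dets$score)
  d <- dets[ord, , drop = FALSE]
  taken <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(d))
  for (i in seq_len(nrow(d))) {
    best <- -1; bi <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j] || gts$image[j] != d$image[i] || gts$class[j] != d$class[i]) next
      iou <- oracle_pair_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                             as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
      if (iou > best) { best <- iou; bi <- j }
    }
    if (bi > 0 && best >= thr) { tp[i] <- TRUE; taken[bi] <- TRUE }
  }
  tp
}

oracle_ap <- function(tp, n_gt, grid = seq(0, 1, by = 0.01)) {
  if (!length(tp) || n_gt == 0) return(0)
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  rec <- ctp / n_gt; prec <- ctp / (ctp + cfp)
  vals <- sapply(grid, function(r) {
    sel <- rec >= r
    if (any(sel)) max(prec[sel]) else 0
  })
  mean(vals)
}

oracle_map <- function(dets, gts, thresholds = seq(0.5, 0.95, 0.05)) {
  classes <- sort(unique(gts$class))
  ap <- sapply(thresholds, function(t) {
    mean(sapply(classes, function(cl) {
      d <- dets[dets$class == cl, , drop = FALSE]
      g <- gts[gts$class == cl, , drop = FALSE]
      oracle_ap(oracle_match(d, g, t), nrow(g))
    }))
  })
  list(map50 = ap[1], map50_95 = mean(ap), ap = ap)
}

# A tiny phantom spec for fast training tests.
tiny_spec <- function(size = 64L) {
  phantom_spec(n_train = 8L, n_val = 2L, size = size,
               canals = c(1L, 1L), canal_width = c(12, 18),
               voids = c(1L, 1L), void_diam = c(5, 9),
               canal_contrast = c(0.45, 0.55), void_contrast = c(0.40, 0.50),
               blur_sigma = c(0.4, 0.6), noise_sd = 0.01)
}

random_dets <- function(n, images, classes = 0L, hi = 100) {
  data.frame(image = sample(images, n, replace = TRUE),
             class = sample(classes, n, replace = TRUE),
             score = runif(n),
             t(replicate(n, random_box(hi = hi))) |>
               `colnames<-`(c("x1", "y1", "x2", "y2")))
}

random_gts <- function(n, images, classes = 0L, hi = 100) {
  data.frame(image = sample(images, n, replace = TRUE),
             class = sample(classes, n, replace = TRUE),
             t(replicate(n, random_box(hi = hi))) |>
               `colnames<-`(c("x1", "y1", "x2", "y2")))
}
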