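# Synthetic radiograph phantom generator.  The phantom emulates appearance
# statistics of periapical radiographs after root-canal obturation: a dark,
# weakly textured tissue background, one to three bright, tapering,
# curved canal bands (radiopaque filling), and small darker elliptical
# voids fully inside a canal.  It models the small-object scale regime
# (voids of a few to ~30 px at 640 x 640), not dental anatomy.

#' Specification of the phantom dataset
#'
#' Defaults emulate the study conditions: 612 training + 156 validation
#' images of 640 x 640 px, 1-3 canals per image, 0-4 voids of 4-28 px.
#'
#' @param n_train,n_val Image counts for the train/val split.
#' @param size Image side length in pixels.
#' @param canals Range (min, max) of canals per image.
#' @param canal_width Range of canal widths in px (at the crown end).
#' @param voids Range of void counts per image.
#' @param void_diam Range of void diameters in px.
#' @param canal_contrast Range of canal brightness above background (0-1 scale).
#' @param void_contrast Range of void darkening relative to the canal.
#' @param blur_sigma Range of Gaussian blur sigmas (px).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Default seed for dataset generation.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_train = 612L, n_val = 156L, size = 640L,
                         canals = c(1L, 3L), canal_width = c(18, 44),
                         voids = c(0L, 4L), void_diam = c(4, 28),
                         canal_contrast = c(0.35, 0.55),
                         void_contrast = c(0.25, 0.45),
                         blur_sigma = c(0.6, 1.5), noise_sd = 0.03,
                         seed = 1234L) {
  rng_ok <- function(r) length(r) == 2L && all(is.finite(r)) && r[1] <= r[2]
  stopifnot(n_train >= 0, n_val >= 0, size >= 32,
            rng_ok(canals), canals[1] >= 1,
            rng_ok(canal_width), canal_width[1] > 0,
            rng_ok(voids), voids[1] >= 0,
            rng_ok(void_diam), void_diam[1] > 0,
            rng_ok(canal_contrast), canal_contrast[1] > 0,
            rng_ok(void_contrast), void_contrast[1] > 0,
            rng_ok(blur_sigma), blur_sigma[1] >= 0, noise_sd >= 0)
  if (void_diam[1] > 0.85 * canal_width[2]) {
    stop("infeasible geometry: smallest void diameter (", void_diam[1],
         " px) does not fit inside the widest canal (", canal_width[2], " px)")
  }
  if (void_diam[2] >= size) stop("void diameter must be smaller than the canal length")
  structure(list(n_train = as.integer(n_train), n_val = as.integer(n_val),
                 size = as.integer(size), canals = canals,
                 canal_width = canal_width, voids = voids, void_diam = void_diam,
                 canal_contrast = canal_contrast, void_contrast = void_contrast,
                 blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' An easier phantom regime for desk-scale learning demos
#'
#' High contrast, low noise, mild blur, 1-2 well-separated voids of 8-20 px
#' at 160 x 160: a learnable small-object task for the CPU-scale detector.
#'
#' @param size Image side length (default 160).
#' @return A `phantom_spec`.
#' @export
phantom_spec_easy <- function(size = 160L) {
  phantom_spec(n_train = 64L, n_val = 16L, size = size,
               canals = c(1L, 2L), canal_width = c(24, 40),
               voids = c(1L, 2L), void_diam = c(8, 20),
               canal_contrast = c(0.45, 0.55), void_contrast = c(0.40, 0.50),
               blur_sigma = c(0.4, 0.8), noise_sd = 0.01)
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  g <- stats::dnorm(seq_len(k) - (k + 1) / 2, sd = sigma)
  g <- g / sum(g)
  d <- dim(m)
  x <- array(m, dim = c(d[1], d[2], 1L, 1L))
  kv <- array(g, dim = c(k, 1L, 1L))
  x <- .dwconv_fwd(x, kv, 0, 1L, k %/% 2L, 0L)
  kh <- array(g, dim = c(1L, k, 1L))
  x <- .dwconv_fwd(x, kh, 0, 1L, 0L, k %/% 2L)
  matrix(x, d[1], d[2])
}

# Low-frequency background texture: bilinear upsampling of a coarse noise grid.
lowfreq_texture <- function(h, w, cells = 8L, amp = 0.1) {
  g <- matrix(stats::runif((cells + 1)^2, 0, amp), cells + 1, cells + 1)
  ys <- (seq_len(h) - 0.5) / h * cells + 0.5
  xs <- (seq_len(w) - 0.5) / w * cells + 0.5
  y0 <- pmin(pmax(floor(ys), 1), cells); x0 <- pmin(pmax(floor(xs), 1), cells)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fyr <- rep(fy, w); fxr <- rep(fx, each = h)
  matrix(a * (1 - fyr) * (1 - fxr) + b * fyr * (1 - fxr) +
           cc * (1 - fyr) * fxr + d * fyr * fxr, h, w)
}

#' Generate one labeled phantom radiograph
#'
#' Deterministic given `(spec, seed)`.  Annotations are tight boxes around
#' the voids *before* blur and noise are applied; blur shifts apparent edges
#' by under 2 px at the default sigmas, mirroring clinical annotation
#' uncertainty.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @param id Image identifier string.
#' @return A `labeled_image`: list with `image` (H x W matrix in `[0, 1]`),
#'   `annotations` (data frame `class`, `cx`, `cy`, `w`, `h`, normalized),
#'   and `id`; attribute `"canal_mask"` holds the logical canal mask.
#' @export
generate_phantom <- function(spec, seed = spec$seed, id = sprintf("phantom_%06d", seed)) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    H <- spec$size; W <- spec$size
    img <- 0.16 + lowfreq_texture(H, W, 8L, 0.1)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    yy <- seq_len(H)
    n_can <- if (spec$canals[1] == spec$canals[2]) spec$canals[1] else
      sample(spec$canals[1]:spec$canals[2], 1L)
    # canal geometry, kept for void placement
    canals <- vector("list", n_can)
    mask <- matrix(FALSE, H, W)
    slot <- W / n_can
    for (k in seq_len(n_can)) {
      x0 <- (k - 0.5) * slot + stats::runif(1, -0.15, 0.15) * slot
      amp <- stats::runif(1, 0.02, 0.08) * W
      freq <- stats::runif(1, 0.5, 1.5)
      phase <- stats::runif(1, 0, 2 * pi)
      slope <- stats::runif(1, -0.06, 0.06)
      cx <- x0 + amp * sin(2 * pi * freq * yy / H + phase) + slope * (yy - H / 2)
      w0 <- runif1(spec$canal_width)
      taper <- stats::runif(1, 0.2, 0.45)
      wv <- w0 * (1 - taper * yy / H)
      contrast <- runif1(spec$canal_contrast)
      dist <- abs(xs - cx)              # cx recycles along rows
      soft <- pmin(1, pmax(0, (wv / 2 - dist) / 1.5 + 0.5))
      img <- img + contrast * soft
      mask <- mask | (dist < wv / 2)
      canals[[k]] <- list(cx = cx, w = wv)
    }
    n_voids <- if (spec$voids[1] == spec$voids[2]) spec$voids[1] else
      sample(spec$voids[1]:spec$voids[2], 1L)
    ann <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
    boxes <- matrix(0, 0, 4)
    placed <- 0L
    tries <- 0L
    while (placed < n_voids && tries < 60L) {
      tries <- tries + 1L
      k <- sample.int(n_can, 1L)
      yv <- round(stats::runif(1, 0.12 * H, 0.92 * H))
      wloc <- canals[[k]]$w[yv]
      dmax <- min(spec$void_diam[2], 0.85 * wloc)
      if (dmax < spec$void_diam[1]) next
      d <- stats::runif(1, spec$void_diam[1], dmax)
      rx <- d / 2
      ry <- rx * stats::runif(1, 1.0, 1.5)
      xv <- canals[[k]]$cx[yv] + stats::runif(1, -1, 1) * max(0, wloc / 2 - rx - 1)
      box <- c(xv - rx, yv - ry, xv + rx, yv + ry)
      if (box[1] < 1 || box[2] < 1 || box[3] > W || box[4] > H) next
      if (nrow(boxes) > 0 && any(box_iou(matrix(box, 1), boxes) > 0)) next
      # carve the void: soft ellipse, darker than the canal
      r0 <- max(1L, floor(box[2] - 2)); r1 <- min(H, ceiling(box[4] + 2))
      c0 <- max(1L, floor(box[1] - 2)); c1 <- min(W, ceiling(box[3] + 2))
      ywin <- r0:r1; xwin <- c0:c1
      e <- sqrt(outer(((ywin - yv) / ry)^2, ((xwin - xv) / rx)^2, `+`))
      softv <- pmax(0, pmin(1, (1 - e) / 0.25))
      vcontrast <- runif1(spec$void_contrast)
      img[ywin, xwin] <- img[ywin, xwin] - vcontrast * softv
      boxes <- rbind(boxes, box)
      ann <- rbind(ann, data.frame(class = 0L, cx = xv / W, cy = yv / H,
                                   w = (box[3] - box[1]) / W,
                                   h = (box[4] - box[2]) / H))
      placed <- placed + 1L
    }
    img <- gaussian_blur(img, runif1(spec$blur_sigma))
    if (spec$noise_sd > 0) img <- img + stats::rnorm(H * W, 0, spec$noise_sd)
    img <- matrix(pmin(1, pmax(0, img)), H, W)
    structure(list(image = img, annotations = ann, id = id),
              canal_mask = mask, class = "labeled_image")
  })
}

#' Convert normalized annotations to pixel corner boxes
#'
#' @param ann Annotation data frame (`class`, `cx`, `cy`, `w`, `h`, normalized).
#' @param h,w Image height and width in pixels.
#' @return An n x 4 matrix of `(x1, y1, x2, y2)` pixel boxes.
#' @export
ann_to_boxes <- function(ann, h, w) {
  if (nrow(ann) == 0L) return(matrix(numeric(), 0, 4,
                                     dimnames = list(NULL, c("x1", "y1", "x2", "y2"))))
  cbind(x1 = (ann$cx - ann$w / 2) * w, y1 = (ann$cy - ann$h / 2) * h,
        x2 = (ann$cx + ann$w / 2) * w, y2 = (ann$cy + ann$h / 2) * h)
}

boxes_to_ann <- function(boxes, h, w, class = 0L) {
  if (nrow(boxes) == 0L) return(data.frame(class = integer(), cx = numeric(),
                                           cy = numeric(), w = numeric(), h = numeric()))
  data.frame(class = class,
             cx = (boxes[, 1] + boxes[, 3]) / 2 / w,
             cy = (boxes[, 2] + boxes[, 4]) / 2 / h,
             w = (boxes[, 3] - boxes[, 1]) / w,
             h = (boxes[, 4] - boxes[, 2]) / h)
}
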