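# Dataset generation, YOLO-format label I/O, mosaic augmentation, and
# letterbox resizing.

#' Write annotations in YOLO text format
#'
#' One `class cx cy w h` line per object, normalized coordinates in
#' 6-decimal fixed format.  An empty annotation set yields an empty file.
#'
#' @param ann Annotation data frame (`class`, `cx`, `cy`, `w`, `h`).
#' @param path Output path.
#' @export
write_yolo_labels <- function(ann, path) {
  if (nrow(ann) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (any(ann$w <= 0 | ann$h <= 0)) stop("annotations must have positive width and height")
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", ann$class, ann$cx, ann$cy, ann$w, ann$h),
             path)
  invisible(path)
}

#' Read annotations from a YOLO text file
#'
#' @param path File path.
#' @return Annotation data frame; zero rows for an empty file.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  if (!length(lines)) return(empty)
  out <- empty
  for (i in seq_along(lines)) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 5L || any(!is.finite(f))) {
      stop("malformed YOLO label at line ", i, " of ", path, ": '", lines[i], "'")
    }
    if (f[4] <= 0 || f[5] <= 0) {
      stop("invalid YOLO label at line ", i, " of ", path,
           ": width and height must be positive")
    }
    if (any(f[2:5] < 0) || any(f[2:5] > 1)) {
      stop("invalid YOLO label at line ", i, " of ", path,
           ": coordinates must be normalized to [0, 1]")
    }
    out <- rbind(out, data.frame(class = as.integer(f[1]), cx = f[2], cy = f[3],
                                 w = f[4], h = f[5]))
  }
  out
}

#' Generate a phantom dataset on disk
#'
#' Writes PNG images and YOLO labels under `out_dir/images/{train,val}` and
#' `out_dir/labels/{train,val}` with a random image-level split, plus a
#' `dataset.yaml` manifest.  With the default spec the split is exactly
#' 612 train / 156 val; when `n` is given instead, the validation share is
#' `floor(0.2 * n)`.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @param n Optional total image count overriding the spec's counts.
#' @param seed Split/generation seed (default `spec$seed`).
#' @return The manifest, invisibly (list with paths, counts, seed).
#' @export
generate_dataset <- function(spec, out_dir, n = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L) stop("output directory not writable: ", out_dir)
  if (is.null(n)) {
    n_val <- spec$n_val; n_total <- spec$n_train + spec$n_val
  } else {
    n_total <- as.integer(n); n_val <- as.integer(floor(0.2 * n_total))
  }
  n_train <- n_total - n_val
  for (sub in c("images/train", "images/val", "labels/train", "labels/val")) {
    dir.create(file.path(out_dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  idx_val <- with_seed(seed, sample.int(n_total, n_val))
  is_val <- seq_len(n_total) %in% idx_val
  for (i in seq_len(n_total)) {
    sub <- if (is_val[i]) "val" else "train"
    id <- sprintf("img_%06d", i)
    li <- generate_phantom(spec, seed = (seed + i) %% 2147483647L, id = id)
    png::writePNG(li$image, file.path(out_dir, "images", sub, paste0(id, ".png")))
    write_yolo_labels(li$annotations, file.path(out_dir, "labels", sub, paste0(id, ".txt")))
  }
  manifest <- list(path = ".", train = "images/train", val = "images/val",
                   names = list(`0` = "void"),
                   n_train = n_train, n_val = n_val, split_seed = as.integer(seed),
                   image_size = spec$size)
  yaml::write_yaml(manifest, file.path(out_dir, "dataset.yaml"))
  invisible(c(manifest, list(dir = out_dir)))
}

#' Load a dataset directory into memory
#'
#' @param dir Dataset directory written by [generate_dataset()].
#' @param split `"train"` or `"val"`.
#' @return List of `labeled_image` objects.
#' @export
load_dataset <- function(dir, split = c("train", "val")) {
  split <- match.arg(split)
  imdir <- file.path(dir, "images", split)
  files <- sort(list.files(imdir, pattern = "\\.png$"))
  lapply(files, function(f) {
    id <- sub("\\.png$", "", f)
    img <- png::readPNG(file.path(imdir, f))
    if (length(dim(img)) == 3L) img <- img[, , 1]
    ann <- read_yolo_labels(file.path(dir, "labels", split, paste0(id, ".txt")))
    structure(list(image = img, annotations = ann, id = id), class = "labeled_image")
  })
}

bilinear_resize <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax((seq_len(th) - 0.5) * h / th + 0.5, 1), h)
  xcs <- pmin(pmax((seq_len(tw) - 0.5) * w / tw + 0.5, 1), w)
  y0 <- pmin(floor(ys), h - 1); fy <- ys - y0
  x0 <- pmin(floor(xcs), w - 1); fx <- xcs - x0
  if (h == 1L) { y0 <- rep(1, th); fy <- rep(0, th) }
  if (w == 1L) { x0 <- rep(1, tw); fx <- rep(0, tw) }
  rows <- m[y0, , drop = FALSE] * (1 - fy) + m[pmin(y0 + 1, h), , drop = FALSE] * fy
  out <- rows[, x0, drop = FALSE] * rep(1 - fx, each = th) +
    rows[, pmin(x0 + 1, w), drop = FALSE] * rep(fx, each = th)
  out
}

#' Mosaic augmentation of four labeled images
#'
#' The four images are scaled into the four quadrants around a randomly
#' jittered center point on an `out_size` canvas; annotations are remapped
#' by the same affine maps, clipped to the canvas, and dropped when their
#' clipped area falls below 1 px^2.
#'
#' @param items List of four `labeled_image` objects.
#' @param out_size Canvas side length (default: side of the first image).
#' @param seed Integer seed for the center jitter.
#' @param jitter Maximal center offset as a fraction of `out_size`.
#' @return A `labeled_image` on the mosaic canvas.
#' @export
mosaic_augment <- function(items, out_size = nrow(items[[1]]$image), seed = 0L,
                           jitter = 1 / 8) {
  stopifnot(length(items) == 4L)
  t <- as.integer(out_size)
  ctr <- with_seed(seed, round(t / 2 + stats::runif(2, -jitter * t, jitter * t)))
  cx <- min(max(ctr[1], 2L), t - 2L); cy <- min(max(ctr[2], 2L), t - 2L)
  canvas <- matrix(0.5, t, t)
  quads <- list(c(1, cy, 1, cx), c(1, cy, cx + 1, t),
                c(cy + 1, t, 1, cx), c(cy + 1, t, cx + 1, t))
  ann_all <- NULL
  for (k in 1:4) {
    q <- quads[[k]]
    qh <- q[2] - q[1] + 1L; qw <- q[4] - q[3] + 1L
    li <- items[[k]]
    h <- nrow(li$image); w <- ncol(li$image)
    canvas[q[1]:q[2], q[3]:q[4]] <- bilinear_resize(li$image, qh, qw)
    if (nrow(li$annotations) > 0L) {
      b <- ann_to_boxes(li$annotations, h, w)
      sx <- qw / w; sy <- qh / h
      b2 <- cbind(b[, 1] * sx + q[3] - 1, b[, 2] * sy + q[1] - 1,
                  b[, 3] * sx + q[3] - 1, b[, 4] * sy + q[1] - 1)
      b2[, c(1, 3)] <- pmin(pmax(b2[, c(1, 3)], 0), t)
      b2[, c(2, 4)] <- pmin(pmax(b2[, c(2, 4)], 0), t)
      keep <- (b2[, 3] - b2[, 1]) * (b2[, 4] - b2[, 2]) >= 1
      if (any(keep)) {
        a2 <- boxes_to_ann(b2[keep, , drop = FALSE], t, t,
                           class = li$annotations$class[keep])
        ann_all <- if (is.null(ann_all)) a2 else rbind(ann_all, a2)
      }
    }
  }
  if (is.null(ann_all)) {
    ann_all <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                          w = numeric(), h = numeric())
  }
  structure(list(image = canvas, annotations = ann_all,
                 id = paste0("mosaic_", items[[1]]$id)),
            class = "labeled_image")
}

#' Letterbox resize to a square target
#'
#' Aspect-preserving scaling to the longer side, then symmetric gray
#' padding to `target x target`.  Annotations are remapped exactly and the
#' inverse mapping is recorded in the `"letterbox"` attribute.
#'
#' @param img A `labeled_image`.
#' @param target Target side length in pixels.
#' @param fill Padding intensity (default 0.5).
#' @return A `labeled_image` of size `target x target`.
#' @export
letterbox_resize <- function(img, target, fill = 0.5) {
  stopifnot(target > 0)
  h <- nrow(img$image); w <- ncol(img$image)
  scale <- target / max(h, w)
  nh <- as.integer(round(h * scale)); nw <- as.integer(round(w * scale))
  pad_y <- (target - nh) %/% 2L; pad_x <- (target - nw) %/% 2L
  canvas <- matrix(fill, target, target)
  canvas[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- bilinear_resize(img$image, nh, nw)
  ann <- img$annotations
  if (nrow(ann) > 0L) {
    b <- ann_to_boxes(ann, h, w)
    b2 <- cbind(b[, 1] * scale + pad_x, b[, 2] * scale + pad_y,
                b[, 3] * scale + pad_x, b[, 4] * scale + pad_y)
    ann <- boxes_to_ann(b2, target, target, class = ann$class)
  }
  structure(list(image = canvas, annotations = ann, id = img$id),
            letterbox = list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                             orig_h = h, orig_w = w),
            class = "labeled_image")
}

#' Map boxes from letterbox coordinates back to the original image
#'
#' @param boxes n x 4 matrix of `(x1, y1, x2, y2)` in letterbox pixels.
#' @param mapping The `"letterbox"` attribute recorded by [letterbox_resize()].
#' @return n x 4 matrix in original-image pixels.
#' @export
letterbox_invert <- function(boxes, mapping) {
  cbind((boxes[, 1] - mapping$pad_x) / mapping$scale,
        (boxes[, 2] - mapping$pad_y) / mapping$scale,
        (boxes[, 3] - mapping$pad_x) / mapping$scale,
        (boxes[, 4] - mapping$pad_y) / mapping$scale)
}
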