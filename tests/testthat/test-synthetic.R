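# Phantom generation, YOLO label I/O, mosaic, and letterbox.

test_that("phantom generation is deterministic and annotation-consistent", {
  spec <- phantom_spec_easy()
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$image, generate_phantom(spec, seed = 8)$image))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # forcing zero voids yields an empty annotation set
  s0 <- phantom_spec(n_train = 1, n_val = 0, size = 160, voids = c(0L, 0L),
                     canal_width = c(24, 40), void_diam = c(8, 20))
  expect_equal(nrow(generate_phantom(s0, seed = 1)$annotations), 0)
})

test_that("every annotation lies inside the image and on a canal", {
  spec <- phantom_spec_easy()
  for (seed in 1:25) {
    li <- generate_phantom(spec, seed = seed)
    mask <- attr(li, "canal_mask")
    ann <- li$annotations
    if (nrow(ann) == 0) next
    b <- ann_to_boxes(ann, 160, 160)
    expect_true(all(b[, 1] >= 0 & b[, 2] >= 0 & b[, 3] <= 160 & b[, 4] <= 160))
    expect_true(all((b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) >= 1))
    # the void center must sit on the canal band
    for (i in seq_len(nrow(b))) {
      expect_true(mask[round((b[i, 2] + b[i, 4]) / 2), round((b[i, 1] + b[i, 3]) / 2)])
    }
  }
})

test_that("voids are darker than the surrounding canal by the configured contrast", {
  spec <- phantom_spec_easy()
  diffs <- c()
  for (seed in 1:100) {
    li <- generate_phantom(spec, seed = seed)
    b <- ann_to_boxes(li$annotations, 160, 160)
    for (i in seq_len(nrow(b))) {
      cx <- (b[i, 1] + b[i, 3]) / 2; cy <- (b[i, 2] + b[i, 4]) / 2
      wq <- (b[i, 3] - b[i, 1]) / 4; hq <- (b[i, 4] - b[i, 2]) / 4
      inner <- li$image[round(cy - hq):round(cy + hq), round(cx - wq):round(cx + wq)]
      ring <- li$image[max(1, round(b[i, 2] - 6)):min(160, round(b[i, 4] + 6)),
                       max(1, round(b[i, 1] - 6)):min(160, round(b[i, 3] + 6))]
      diffs <- c(diffs, mean(ring) - mean(inner))
    }
  }
  # the inner half of the void box averages at least half the configured
  # minimum contrast below its surroundings (soft edges and blur dilute the
  # nominal contrast; noise allowance included in the margin)
  expect_gt(length(diffs), 50)
  expect_gt(mean(diffs), 0.5 * spec$void_contrast[1] - spec$noise_sd)
  expect_gt(stats::quantile(diffs, 0.1), 0.25 * spec$void_contrast[1])
})

test_that("infeasible phantom geometry is rejected", {
  expect_error(phantom_spec(void_diam = c(50, 60), canal_width = c(10, 20)),
               "infeasible")
  expect_error(phantom_spec(size = 64, void_diam = c(4, 70), canal_width = c(60, 90)),
               "smaller than the canal")
})

test_that("YOLO labels round-trip losslessly at 6-decimal precision", {
  f <- tempfile(fileext = ".txt")
  empty <- data.frame(class = integer(), cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric())
  write_yolo_labels(empty, f)
  expect_equal(nrow(read_yolo_labels(f)), 0)
  ann <- data.frame(class = 0L, cx = 0.5, cy = 0.5, w = 0.1, h = 0.2)
  write_yolo_labels(ann, f)
  expect_equal(read_yolo_labels(f), ann)
  set.seed(31)
  ann <- data.frame(class = rep(0L, 20), cx = runif(20, 0.2, 0.8),
                    cy = runif(20, 0.2, 0.8), w = runif(20, 0.01, 0.3),
                    h = runif(20, 0.01, 0.3))
  write_yolo_labels(ann, f)
  got <- read_yolo_labels(f)
  for (col in c("cx", "cy", "w", "h")) {
    expect_lt(max(abs(got[[col]] - ann[[col]])), 1e-6)
  }
  writeLines("0 0.5 0.5 0 0.1", f)
  expect_error(read_yolo_labels(f), "line 1")
  writeLines(c("0 0.5 0.5 0.1 0.1", "0 0.5 abc 0.1"), f)
  expect_error(read_yolo_labels(f), "line 2")
  expect_error(write_yolo_labels(data.frame(class = 0L, cx = .5, cy = .5,
                                            w = 0, h = .1), f), "positive")
})

test_that("dataset generation writes the declared split and reproduces it", {
  spec <- tiny_spec()
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  man <- generate_dataset(spec, d1, n = 10, seed = 5)
  expect_equal(man$n_train, 8); expect_equal(man$n_val, 2)
  expect_equal(length(list.files(file.path(d1, "images/train"))), 8)
  expect_equal(length(list.files(file.path(d1, "images/val"))), 2)
  expect_true(file.exists(file.path(d1, "dataset.yaml")))
  generate_dataset(spec, d2, n = 10, seed = 5)
  expect_identical(list.files(file.path(d1, "images/val")),
                   list.files(file.path(d2, "images/val")))
  expect_identical(readBin(list.files(file.path(d1, "images/train"), full.names = TRUE)[1],
                           "raw", 1e6),
                   readBin(list.files(file.path(d2, "images/train"), full.names = TRUE)[1],
                           "raw", 1e6))
  # loading round-trips images and labels
  tr <- load_dataset(d1, "train")
  expect_equal(length(tr), 8)
  expect_true(all(vapply(tr, function(li) all(dim(li$image) == 64), logical(1))))
})

test_that("mosaic places each source in its quadrant and keeps every surviving box", {
  spec <- tiny_spec()
  items <- lapply(1:4, function(i) generate_phantom(spec, seed = 100 + i))
  mz <- mosaic_augment(items, out_size = 64, seed = 3)
  expect_s3_class(mz, "labeled_image")
  expect_equal(dim(mz$image), c(64, 64))
  n_src <- sum(vapply(items, function(li) nrow(li$annotations), integer(1)))
  expect_lte(nrow(mz$annotations), n_src)
  expect_identical(mosaic_augment(items, out_size = 64, seed = 3), mz)
  # zero jitter and equal quadrants: each box is the original scaled by 1/2
  # and translated by its quadrant offset
  m0 <- mosaic_augment(items, out_size = 64, seed = 1, jitter = 0)
  offs <- list(c(0, 0), c(32, 0), c(0, 32), c(32, 32))
  expected <- do.call(rbind, lapply(1:4, function(k) {
    b <- ann_to_boxes(items[[k]]$annotations, 64, 64) / 2
    b + rep(c(offs[[k]][1], offs[[k]][2]), 2)[col(b)]
  }))
  got <- ann_to_boxes(m0$annotations, 64, 64)
  expect_equal(got[order(got[, 1], got[, 2]), ],
               expected[order(expected[, 1], expected[, 2]), ],
               tolerance = 1e-6, ignore_attr = TRUE)
  # four identical single-void sources: at most 4 voids, each in its quadrant
  one <- generate_phantom(spec, seed = 200)
  m1 <- mosaic_augment(list(one, one, one, one), out_size = 64, seed = 2)
  expect_lte(nrow(m1$annotations), 4)
})

test_that("letterbox resizing is exact and invertible on annotations", {
  spec <- tiny_spec()
  li <- generate_phantom(spec, seed = 9)
  # square input: plain scaling, no padding
  lb <- letterbox_resize(li, 128)
  mp <- attr(lb, "letterbox")
  expect_equal(mp$scale, 2); expect_equal(mp$pad_x, 0); expect_equal(mp$pad_y, 0)
  expect_equal(dim(lb$image), c(128, 128))
  # rectangular input: pad the short side symmetrically
  wide <- structure(list(image = matrix(runif(320 * 640), 320, 640),
                         annotations = data.frame(class = 0L, cx = 0.5, cy = 0.5,
                                                  w = 0.1, h = 0.1),
                         id = "wide"), class = "labeled_image")
  lbw <- letterbox_resize(wide, 640)
  mpw <- attr(lbw, "letterbox")
  expect_equal(mpw$scale, 1)
  expect_equal(mpw$pad_y, 160); expect_equal(mpw$pad_x, 0)
  b0 <- ann_to_boxes(wide$annotations, 320, 640)
  b1 <- ann_to_boxes(lbw$annotations, 640, 640)
  expect_equal(b1, b0 + rep(c(0, 160), 2)[col(b1)], ignore_attr = TRUE)
  expect_equal(letterbox_invert(b1, mpw), b0, ignore_attr = TRUE)
  # remap -> inverse remap is the identity
  b2 <- ann_to_boxes(lb$annotations, 128, 128)
  expect_equal(letterbox_invert(b2, mp),
               ann_to_boxes(li$annotations, 64, 64), tolerance = 1e-9,
               ignore_attr = TRUE)
})
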