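# Box geometry and the CIoU / MPDIoU / CMIoU loss family.

test_that("IoU handles identity, disjointness, partial overlap, and degeneracy", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15)), 25 / 175)
  # rasterization oracle on the partial-overlap case
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15)),
               oracle_iou_grid(c(0, 0, 10, 10), c(5, 5, 15, 15)),
               tolerance = 1e-2)
  # both boxes degenerate: 0/0 defined as 0
  expect_equal(box_iou(c(3, 3, 3, 3), c(3, 3, 3, 3)), 0)
  # symmetry on random pairs
  set.seed(11)
  for (i in 1:50) {
    a <- random_box(); b <- random_box()
    expect_identical(box_iou(a, b), box_iou(b, a))
  }
})

test_that("invalid boxes are rejected with a precise message", {
  expect_error(box_iou(c(10, 0, 0, 10), c(0, 0, 1, 1)), "x1 <= x2")
  expect_error(ciou_loss(c(0, 0, 1, 1), c(0, 0, 0, 5)), "degenerate")
  expect_error(cmiou_loss(c(0, 0, 1, 1), c(2, 2, 2, 2), image_frame(10, 10)),
               "degenerate")
  expect_error(image_frame(0, 100), "positive")
  expect_error(mpdiou(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 100)), "positive")
})

test_that("CIoU matches hand-derived and scripted evaluations", {
  b <- ciou_loss(c(0, 0, 10, 10), c(0, 0, 10, 10))
  expect_equal(b$total, 0)
  expect_equal(b$iou, 1)
  expect_equal(b$v, 0)
  # side-by-side squares: IoU 0, centers 10 apart, enclosing 20 x 10
  b <- ciou_loss(c(0, 0, 10, 10), c(10, 0, 20, 10))
  expect_equal(b$iou, 0)
  expect_equal(b$rho2, 100)
  expect_equal(b$c2, 500)
  expect_equal(b$alpha, 0)
  expect_equal(b$total, 1.2)
  # aspect-ratio penalty is active for rotated aspect
  b <- ciou_loss(c(0, 0, 10, 20), c(0, 0, 20, 10))
  expect_equal(b$v, (4 / pi^2) * (atan(2) - atan(1 / 2))^2)
  expect_gt(b$total, 1 - b$iou + b$rho2 / b$c2)
})

test_that("corner distances match hand arithmetic and are translation invariant", {
  expect_equal(unname(mpdiou_terms(c(0, 0, 10, 10), c(0, 0, 10, 10))[1, ]), c(0, 0))
  expect_equal(unname(mpdiou_terms(c(0, 0, 10, 10), c(10, 0, 20, 10))[1, ]),
               c(100, 100))
  set.seed(5)
  for (i in 1:20) {
    a <- random_box(); b <- random_box(); off <- runif(2, -30, 30)
    sh <- c(off[1], off[2], off[1], off[2])
    expect_equal(mpdiou_terms(a + sh, b + sh), mpdiou_terms(a, b))
  }
})

test_that("MPDIoU is the printed similarity: IoU minus normalized corner distance", {
  expect_equal(mpdiou(c(0, 0, 10, 10), c(0, 0, 10, 10), image_frame(77, 33)), 1)
  expect_equal(mpdiou(c(0, 0, 10, 10), c(10, 0, 20, 10), image_frame(100, 100)), -0.01)
  # doubling the frame quadruples the normalizer -> penalty shrinks 4x
  p <- c(0, 0, 10, 10); g <- c(30, 40, 44, 52)
  pen1 <- box_iou(p, g) - mpdiou(p, g, image_frame(100, 100))
  pen2 <- box_iou(p, g) - mpdiou(p, g, image_frame(200, 200))
  expect_equal(pen1 / pen2, 4)
})

test_that("CMIoU equals the sum of its parts and is zero iff boxes coincide", {
  b <- cmiou_loss(c(0, 0, 10, 10), c(10, 0, 20, 10), image_frame(100, 100))
  expect_equal(b$total, 1.21)
  expect_equal(b$mpd_penalty, 0.01)
  set.seed(21)
  for (i in 1:200) {
    g <- random_box()
    expect_equal(cmiou_loss(g, g, image_frame(100, 100))$total, 0)
    p <- random_box()
    if (!isTRUE(all.equal(p, g))) {
      expect_gt(cmiou_loss(p, g, image_frame(100, 100))$total, 0)
    }
  }
})

test_that("breakdown fields obey their range invariants on random pairs", {
  set.seed(31)
  for (i in 1:200) {
    b <- cmiou_loss(random_box(), random_box(), image_frame(100, 100))
    expect_gte(b$iou, 0); expect_lte(b$iou, 1)
    expect_lte(b$rho2, b$c2 + 1e-12)  # center offset bounded by enclosing diagonal
    expect_gte(b$v, 0); expect_gte(b$alpha, 0)
    expect_gte(b$d1sq, 0); expect_gte(b$d2sq, 0); expect_gte(b$mpd_penalty, 0)
    if (b$v == 0 && b$iou < 1) expect_equal(b$alpha, 0)
  }
})

test_that("per-term breakdowns match the scripted oracle to 1e-9", {
  set.seed(41)
  for (i in 1:300) {
    p <- random_box(); g <- random_box()
    o <- oracle_terms(p, g, 100, 100)
    b <- cmiou_loss(p, g, image_frame(100, 100))
    for (f in c("iou", "rho2", "c2", "v", "alpha", "d1sq", "d2sq")) {
      expect_equal(b[[f]], o[[f]], tolerance = 1e-9)
    }
    expect_equal(b$total, o$cmiou, tolerance = 1e-9)
    expect_equal(ciou_loss(p, g)$total, o$ciou, tolerance = 1e-9)
    expect_equal(mpdiou(p, g, image_frame(100, 100)), o$mpdiou, tolerance = 1e-9)
  }
})

test_that("penalty symmetry: center and corner terms are symmetric, alpha*v is not", {
  set.seed(51)
  for (i in 1:30) {
    p <- random_box(); g <- random_box()
    a <- cmiou_loss(p, g, image_frame(100, 100))
    b <- cmiou_loss(g, p, image_frame(100, 100))
    expect_equal(a$rho2 / a$c2, b$rho2 / b$c2)
    expect_equal(a$mpd_penalty, b$mpd_penalty)
  }
  # the aspect term's value is also exchange-symmetric (the squared arctan
  # difference and the IoU both are); the roles matter only for validation
  # (the ground truth must be non-degenerate) and for gradient treatment
  p <- c(0, 0, 30, 10); g <- c(2, 1, 12, 21)
  a <- cmiou_loss(p, g, image_frame(100, 100))
  b <- cmiou_loss(g, p, image_frame(100, 100))
  expect_equal(a$alpha * a$v, b$alpha * b$v)
  ga <- box_loss_grad(p, g, image_frame(100, 100))
  gb <- box_loss_grad(g, p, image_frame(100, 100))
  expect_false(isTRUE(all.equal(ga, gb)))
})

test_that("translating the prediction away from the target strictly increases the loss", {
  g <- c(20, 20, 35, 33)
  prev <- -Inf
  for (shift in seq(20, 120, by = 5)) {
    p <- g + c(shift, 0, shift, 0)
    cur <- cmiou_loss(p, g, image_frame(200, 200))$total
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("analytic gradients agree with central differences", {
  set.seed(61)
  fr <- image_frame(100, 100)
  for (i in 1:60) {
    p <- random_box(minside = 3); g <- random_box(minside = 3)
    num <- sapply(1:4, function(k) {
      e <- 1e-5
      a <- p; a[k] <- a[k] + e; b <- p; b[k] <- b[k] - e
      (cmiou_loss(a, g, fr)$total - cmiou_loss(b, g, fr)$total) / (2 * e)
    })
    ana <- box_loss_grad(p, g, fr, exact_alpha = TRUE)
    expect_equal(as.numeric(ana), num, tolerance = 1e-4)
    # the training-time gradient (alpha detached) matches differences of the
    # alpha-frozen objective
    o <- cmiou_loss(p, g, fr)
    numd <- sapply(1:4, function(k) {
      e <- 1e-5
      a <- p; a[k] <- a[k] + e; b <- p; b[k] <- b[k] - e
      fa <- cmiou_loss(a, g, fr); fb <- cmiou_loss(b, g, fr)
      ((1 - fa$iou + fa$mpd_penalty + fa$rho2 / fa$c2 + o$alpha * fa$v) -
         (1 - fb$iou + fb$mpd_penalty + fb$rho2 / fb$c2 + o$alpha * fb$v)) / (2 * e)
    })
    expect_equal(as.numeric(box_loss_grad(p, g, fr)), numd, tolerance = 1e-4)
  }
})

test_that("total loss composition is a checked weighted sum", {
  expect_equal(compose_total_loss(0, 0, 0, c(3, 1, 9)), 0)
  expect_equal(compose_total_loss(1, 2, 3, c(1, 1, 1)), 6)
  expect_equal(compose_total_loss(1, 2, 3, c(2, 0.5, 1)), 6)
  # linear in each term
  expect_equal(compose_total_loss(2, 2, 3, c(1, 1, 1)) -
                 compose_total_loss(1, 2, 3, c(1, 1, 1)), 1)
  expect_error(compose_total_loss(1, 1, 1, c(-1, 1, 1)), "non-negative")
  expect_error(compose_total_loss(-1, 1, 1, c(1, 1, 1)), "non-negative")
  expect_error(compose_total_loss(Inf, 1, 1, c(1, 1, 1)), "finite")
})
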