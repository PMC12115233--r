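# ResConv, tokenization, token attention, and the fused C2f-style block.

test_that("ResConv with a silenced depthwise branch reproduces the plain convolution", {
  set.seed(1)
  p <- res_conv_params(3, 5, seed = 10)
  p$dw$w[] <- 0; p$dw$b[] <- 0
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  got <- res_conv_forward(x, p, stride = 1L, normalize = FALSE)
  expect_equal(got, oracle_conv(x, p$conv$w, p$conv$b, 1, 1), tolerance = 1e-6)
  got2 <- res_conv_forward(x, p, stride = 2L, normalize = FALSE)
  expect_equal(got2, oracle_conv(x, p$conv$w, p$conv$b, 2, 1), tolerance = 1e-6)
})

test_that("ResConv shape contract holds across strides and channel counts", {
  p <- res_conv_params(4, 8, seed = 2)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(dim(res_conv_forward(x, p, 1L)), c(8, 8, 8))
  expect_equal(dim(res_conv_forward(x, p, 2L)), c(4, 4, 8))
  expect_error(res_conv_forward(array(0, c(8, 8, 3)), p), "channel mismatch")
  expect_error(res_conv_forward(x, p, stride = 3L), "stride")
})

test_that("ResConv on constant input matches hand-computed affine values", {
  # constant input c and known kernel sums: an interior activation of the
  # conv is b + c * sum(w); the depthwise stage adds its own affine layer
  cin <- 2; cout <- 3; cval <- 0.7
  p <- res_conv_params(cin, cout, seed = 3)
  x <- array(cval, c(7, 7, cin))
  got <- res_conv_forward(x, p, 1L, normalize = FALSE)
  for (co in 1:cout) {
    conv_interior <- p$conv$b[co] + cval * sum(p$conv$w[, , , co])
    dw_interior <- p$dw$b[co] + conv_interior * sum(p$dw$w[, , co])
    expect_equal(got[4, 4, co], conv_interior + dw_interior, tolerance = 1e-10)
  }
})

test_that("tokenize partitions row-major without duplication or loss", {
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  t1 <- tokenize(x, 1)
  expect_equal(t1$tokens[[1]], x)
  # entries 0..15 in row-major reading order
  xr <- array(matrix(0:15, 4, 4, byrow = TRUE), c(4, 4, 1))
  t2 <- tokenize(xr, 2)
  expect_equal(t2$tokens[[1]][, , 1], matrix(c(0, 4, 1, 5), 2, 2))
  expect_equal(t2$tokens[[2]][, , 1], matrix(c(2, 6, 3, 7), 2, 2))
  expect_equal(t2$tokens[[4]][, , 1], matrix(c(10, 14, 11, 15), 2, 2))
  expect_error(tokenize(array(0, c(5, 4, 1)), 2), "H = 5")
})

test_that("tokenize and untokenize are exact mutual inverses", {
  set.seed(7)
  for (S in c(1, 2, 3, 6)) {
    x <- array(rnorm(12 * 6 * 3), c(12, 6, 3))
    if (12 %% S == 0 && 6 %% S == 0) {
      expect_identical(untokenize(tokenize(x, S)), x)
    }
  }
  xr <- array(matrix(0:15, 4, 4, byrow = TRUE), c(4, 4, 1))
  expect_identical(untokenize(tokenize(xr, 2)), xr)
  tg <- tokenize(array(rnorm(8 * 8 * 2), c(8, 8, 2)), 4)
  tg2 <- tokenize(untokenize(tg), 4)
  expect_identical(tg2$tokens, tg$tokens)
  tg$tokens[[2]] <- tg$tokens[[2]][1:1, , , drop = FALSE]
  expect_error(untokenize(tg), "ragged")
})

test_that("token attention computes softmax-weighted sums within each token", {
  C <- 3
  idp <- list(wq = diag(C), wk = diag(C), wv = diag(C))
  # single-pixel token: softmax of a scalar is 1, output = V projection
  x <- array(rnorm(2 * 2 * C), c(2, 2, C))
  tg <- token_attention(tokenize(x, 2), idp)
  expect_equal(untokenize(tg), x, tolerance = 1e-12)
  # identical rows: uniform weights over identical values returns the rows
  xi <- array(rep(rnorm(C), each = 4), c(2, 2, C))
  tgi <- token_attention(tokenize(xi, 1), idp)
  expect_equal(untokenize(tgi), xi, tolerance = 1e-12)
  # two-pixel token against scalar arithmetic
  x2 <- array(rnorm(1 * 2 * C), c(1, 2, C))
  got <- untokenize(token_attention(tokenize(x2, 1), idp))
  X <- matrix(x2, 2, C)
  Z <- (X %*% t(X)) / sqrt(C)
  A <- exp(Z); A <- A / rowSums(A)
  expect_equal(matrix(got, 2, C), A %*% X, tolerance = 1e-12)
  # weight rows sum to 1
  w <- attr(token_attention(tokenize(array(rnorm(4 * 4 * C), c(4, 4, C)), 2), idp),
            "weights")
  for (tok in w) for (A in tok) expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  expect_error(token_attention(tokenize(x, 2), list(wq = diag(2), wk = diag(3),
                                                    wv = diag(3))), "wq")
})

test_that("TokAtt with one token equals global self-attention", {
  C <- 6
  p <- tokatt_params(C, seed = 4)
  p$wo <- matrix(rnorm(C * C, 0, 0.2), C, C)  # un-silence the output projection
  x <- array(rnorm(4 * 4 * C), c(4, 4, C))
  got <- tokatt_forward(x, 1, p)
  # independent composition of the same pipeline over all 16 pixels at once
  Xm <- matrix(x, 16, C)
  E <- sweep(Xm %*% p$we, 2, p$be, `+`)
  mu <- rowMeans(E); v <- rowMeans((E - mu)^2)
  Eh <- (E - mu) / sqrt(v + 1e-6)
  Eh <- sweep(sweep(Eh, 2, p$ln$gamma, `*`), 2, p$ln$beta, `+`)
  Q <- Eh %*% p$wq; K <- Eh %*% p$wk; V <- Eh %*% p$wv
  Z <- Q %*% t(K) / sqrt(C)
  A <- exp(Z - apply(Z, 1, max)); A <- A / rowSums(A)
  O <- sweep((A %*% V) %*% p$wo, 2, p$bo, `+`)
  expect_equal(got, array(O, c(4, 4, C)) + x, tolerance = 1e-5)
})

test_that("TokAtt output blocks permute with input token blocks (shared parameters)", {
  C <- 5; S <- 2
  p <- tokatt_params(C, seed = 9)
  p$wo <- matrix(rnorm(C * C, 0, 0.2), C, C)
  x <- array(rnorm(8 * 8 * C), c(8, 8, C))
  y <- tokatt_forward(x, S, p)
  perm <- c(3, 1, 4, 2)          # fixed permutation of the 4 token blocks
  tgx <- tokenize(x, S); tgx$tokens <- tgx$tokens[perm]
  yp <- tokatt_forward(untokenize(tgx), S, p)
  tgy <- tokenize(y, S); tgy$tokens <- tgy$tokens[perm]
  expect_equal(yp, untokenize(tgy), tolerance = 1e-12)
})

test_that("TokAtt preserves shape and isolates tokens", {
  C <- 4; S <- 4
  p <- tokatt_params(C, seed = 5)
  p$wo <- matrix(rnorm(C * C, 0, 0.2), C, C)
  x <- array(rnorm(8 * 8 * C), c(8, 8, C))
  y <- tokatt_forward(x, S, p)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  # perturb pixels inside token (2, 3): only that block of the output moves
  x2 <- x
  x2[3:4, 5:6, ] <- x2[3:4, 5:6, ] + rnorm(2 * 2 * C)
  y2 <- tokatt_forward(x2, S, p)
  delta <- abs(y2 - y) > 1e-12
  blocks <- tokenize(array(delta + 0, dim(delta)), S)
  for (i in seq_len(S)) for (j in seq_len(S)) {
    b <- blocks$tokens[[(i - 1) * S + j]]
    if (i == 2 && j == 3) expect_gt(sum(b), 0) else expect_equal(sum(b), 0)
  }
  expect_error(tokatt_forward(x, 3, p), "does not divide")
})

test_that("the fused block silences to plain CSP fusion and keeps its shape contract", {
  set.seed(6)
  cin <- 6; cout <- 8
  p <- c2fcs_params(cin, cout, seed = 12)   # output projection zero-initialized
  x <- array(rnorm(8 * 8 * cin), c(8, 8, cin))
  y <- c2fcs_forward(x, p, S = 2)
  expect_equal(dim(y), c(8, 8, cout))
  # compose the plain fusion path with the package's own layers
  x4 <- array(x, c(8, 8, cin, 1))
  s <- rootvoid:::c2fcs_state(p)
  h <- p$h
  c1 <- rootvoid:::cbs_fwd(x4, p$cv1, s$cv1, 1L, TRUE)
  a <- c1$y[, , seq_len(h), , drop = FALSE]
  b <- c1$y[, , h + seq_len(h), , drop = FALSE]
  dwc <- rootvoid:::dwconv_fwd(b, p$cib_dw, 1L)
  bn1 <- rootvoid:::bn_fwd(dwc$y, p$cib_bn1, s$cib_bn1, TRUE)
  ac1 <- rootvoid:::silu_fwd(bn1$y)
  pw <- rootvoid:::cbs_fwd(ac1$y, p$cib_pw, s$cib_pw, 1L, TRUE)
  m <- b + pw$y
  cat2 <- rootvoid:::concat_ch(rootvoid:::concat_ch(a, b)$y, m)
  plain <- rootvoid:::cbs_fwd(cat2$y, p$cv2, s$cv2, 1L, TRUE)$y
  expect_equal(y, plain[, , , 1], tolerance = 1e-12)
  expect_error(c2fcs_forward(array(0, c(8, 8, 3)), p, 2), "channel mismatch")
})

test_that("gradient reaches every parameter group of the fused block", {
  set.seed(8)
  p <- c2fcs_params(5, 6, seed = 13)
  p$att$wo <- matrix(rnorm(36, 0, 0.2), 6, 6)  # activate the attention branch
  x <- array(rnorm(8 * 8 * 5 * 2), c(8, 8, 5, 2))
  fw <- rootvoid:::c2fcs_fwd(x, p, rootvoid:::c2fcs_state(p), S = 2, train = TRUE)
  dy <- array(rnorm(length(fw$y)), dim(fw$y))
  g <- rootvoid:::c2fcs_bwd(dy, fw$cache)$grads
  leaf_norms <- rapply(g, function(v) sum(abs(v)), how = "unlist")
  expect_true(all(leaf_norms > 0))
})

test_that("block outputs stay finite on standard-normal inputs at default init", {
  set.seed(9)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  expect_true(all(is.finite(res_conv_forward(x, res_conv_params(6, 8, seed = 1)))))
  expect_true(all(is.finite(tokatt_forward(x, 2, tokatt_params(6, seed = 1)))))
  expect_true(all(is.finite(c2fcs_forward(x, c2fcs_params(6, 6, seed = 1), S = 2))))
})
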