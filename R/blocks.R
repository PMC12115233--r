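# Building blocks of the detector: the residual convolution block, the
# tokenized-attention block, and the CSP-style fusion block that appends
# token attention to its output.
#
# Exported *_forward functions are the user-facing, single-map surface
# (H x W x C arrays).  Internal *_fwd/*_bwd pairs operate on batched
# (H, W, C, N) tensors and thread BN running-state and backprop caches.

# ---------------------------------------------------------------------------
# ResConv: y = Conv_{3x3, stride}(x); out = SiLU(BN(y + DWConv_{3x3}(y))).
# The additive skip carries the standard-convolution output past the
# depthwise stage, so the block is simultaneously serial (composition) and
# parallel (skip), and stays shape-compatible at any stride.

#' Parameters for a residual convolution block
#'
#' @param cin,cout Input/output channel counts.
#' @param seed Optional integer seed for reproducible initialization.
#' @return Nested parameter list (standard conv, depthwise conv, batch norm).
#' @export
res_conv_params <- function(cin, cout, seed = NULL) {
  make <- function() list(conv = conv_params(cin, cout, 3L),
                          dw = dwconv_params(cout, 3L),
                          bn = bn_params(cout))
  if (is.null(seed)) make() else with_seed(seed, make())
}

res_fwd <- function(x, p, s, stride = 1L, train = TRUE, normalize = TRUE) {
  cv <- conv_fwd(x, p$conv, stride)
  dw <- dwconv_fwd(cv$y, p$dw, 1L)
  z <- cv$y + dw$y
  attributes(z) <- attributes(cv$y)
  if (!normalize) {
    return(list(y = z, s = s, cache = list(cv = cv$cache, dw = dw$cache, normalize = FALSE)))
  }
  bn <- bn_fwd(z, p$bn, s$bn, train)
  ac <- silu_fwd(bn$y)
  list(y = ac$y, s = list(bn = bn$state),
       cache = list(cv = cv$cache, dw = dw$cache, bn = bn$cache, ac = ac$cache,
                    normalize = TRUE))
}

res_bwd <- function(dy, cache, need_input_grad = TRUE) {
  if (cache$normalize) {
    dy <- silu_bwd(dy, cache$ac)$dx
    b <- bn_bwd(dy, cache$bn)
    dz <- b$dx
    bn_g <- b$grads
  } else {
    dz <- dy
    bn_g <- list(gamma = numeric(0), beta = numeric(0))
  }
  dwb <- dwconv_bwd(dz, cache$dw)
  dyy <- dz + dwb$dx
  cvb <- conv_bwd(dyy, cache$cv, need_dx = need_input_grad)
  list(dx = cvb$dx,
       grads = list(conv = cvb$grads, dw = dwb$grads, bn = bn_g))
}

#' Residual convolution block forward pass
#'
#' `SiLU(BN(y + DWConv(y)))` with `y = Conv_{3x3, stride}(x)`: a 3x3 standard
#' convolution whose output is carried by a residual skip past a 3x3
#' depthwise stage, then normalized and activated.  With
#' `normalize = FALSE` the raw `y + DWConv(y)` is returned, so silencing the
#' depthwise kernels recovers the plain convolution exactly.
#'
#' @param x Feature map, `H x W x C` (or batched `H x W x C x N`) array.
#' @param p Parameters from [res_conv_params()].
#' @param stride Convolution stride, 1 or 2.
#' @param normalize Apply batch norm + SiLU after the skip (default `TRUE`).
#' @return Feature map of shape `ceil(H/stride) x ceil(W/stride) x cout`.
#' @export
res_conv_forward <- function(x, p, stride = 1L, normalize = TRUE) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  x4 <- as_t4(x)
  if (dim(x4)[3] != dim(p$conv$w)[3]) {
    stop("channel mismatch: input has ", dim(x4)[3], " channels, block expects ",
         dim(p$conv$w)[3])
  }
  out <- res_fwd(x4, p, list(bn = bn_state(dim(p$conv$w)[4])), stride,
                 train = TRUE, normalize = normalize)$y
  if (length(dim(x)) == 3L || is.null(dim(x))) out <- out[, , , 1, drop = TRUE]
  out
}

# ---------------------------------------------------------------------------
# Tokenization: partition an H x W x C map into an S x S grid of
# non-overlapping (H/S) x (W/S) x C tokens, kept in row-major grid order.

#' Partition a feature map into non-overlapping spatial tokens
#'
#' @param x `H x W x C` array; `S` must divide both `H` and `W`.
#' @param S Tokens per side (the grid is `S x S`).
#' @return A `token_grid`: list of `S^2` arrays of shape `(H/S, W/S, C)` in
#'   row-major grid order, plus grid metadata.
#' @export
tokenize <- function(x, S) {
  if (is.null(dim(x)) || length(dim(x)) != 3L) stop("x must be an H x W x C array")
  d <- dim(x)
  S <- as.integer(S)
  if (S < 1L) stop("S must be a positive integer")
  if (d[1] %% S != 0L || d[2] %% S != 0L) {
    stop(sprintf("S = %d does not divide the feature map: H = %d, W = %d", S, d[1], d[2]))
  }
  th <- d[1] %/% S; tw <- d[2] %/% S
  tokens <- vector("list", S * S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      tokens[[(i - 1L) * S + j]] <-
        x[(i - 1L) * th + seq_len(th), (j - 1L) * tw + seq_len(tw), , drop = FALSE]
    }
  }
  structure(list(tokens = tokens, S = S, th = th, tw = tw, C = d[3]),
            class = "token_grid")
}

#' Reassemble a token grid into a feature map
#'
#' Exact inverse of [tokenize()] (row-major grid placement).
#'
#' @param t A `token_grid`.
#' @return The `H x W x C` array the grid was cut from.
#' @export
untokenize <- function(t) {
  stopifnot(inherits(t, "token_grid"))
  shapes <- vapply(t$tokens, function(z) dim(z), integer(3))
  if (any(shapes[1, ] != t$th) || any(shapes[2, ] != t$tw) || any(shapes[3, ] != t$C)) {
    stop("ragged token grid: all tokens must share the shape (",
         t$th, ", ", t$tw, ", ", t$C, ")")
  }
  x <- array(vector(typeof(t$tokens[[1]]), 1L), dim = c(t$S * t$th, t$S * t$tw, t$C))
  for (i in seq_len(t$S)) {
    for (j in seq_len(t$S)) {
      x[(i - 1L) * t$th + seq_len(t$th), (j - 1L) * t$tw + seq_len(t$tw), ] <-
        t$tokens[[(i - 1L) * t$S + j]]
    }
  }
  x
}

# ---------------------------------------------------------------------------
# Scaled dot-product attention inside one token (optionally multi-head).
# Token pixels are flattened to rows; weights = softmax(Q K' / sqrt(C/heads)).

attn_one_fwd <- function(X, p, heads = 1L) {
  C <- ncol(X)
  Q <- X %*% p$wq; K <- X %*% p$wk; V <- X %*% p$wv
  hs <- C %/% heads
  Y <- matrix(0, nrow(X), C)
  hc <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * hs + seq_len(hs)
    Z <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(hs)
    Z <- Z - apply(Z, 1, max)
    A <- exp(Z); A <- A / rowSums(A)
    Y[, idx] <- A %*% V[, idx, drop = FALSE]
    hc[[h]] <- A
  }
  list(Y = Y, cache = list(X = X, Q = Q, K = K, V = V, A = hc, heads = heads, hs = hs))
}

attn_one_bwd <- function(dY, cache, p) {
  X <- cache$X; heads <- cache$heads; hs <- cache$hs
  dQ <- matrix(0, nrow(X), ncol(X)); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    idx <- (h - 1L) * hs + seq_len(hs)
    A <- cache$A[[h]]
    dYh <- dY[, idx, drop = FALSE]
    dV[, idx] <- crossprod(A, dYh)
    dA <- tcrossprod(dYh, cache$V[, idx, drop = FALSE])
    dZ <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dZ %*% cache$K[, idx, drop = FALSE] / sqrt(hs)
    dK[, idx] <- crossprod(dZ, cache$Q[, idx, drop = FALSE]) / sqrt(hs)
  }
  list(dX = dQ %*% t(p$wq) + dK %*% t(p$wk) + dV %*% t(p$wv),
       dwq = crossprod(X, dQ), dwk = crossprod(X, dK), dwv = crossprod(X, dV))
}

#' Self-attention within each token of a grid
#'
#' Within every token independently: flatten the token's pixels to rows,
#' project to queries/keys/values, form `softmax(Q K' / sqrt(C))` row-wise,
#' and return the weighted sums of values reshaped to the token's spatial
#' shape.  No information crosses token boundaries.
#'
#' @param t A `token_grid`.
#' @param p List with `C x C` projection matrices `wq`, `wk`, `wv` (e.g. from
#'   [tokatt_params()]).
#' @param heads Number of attention heads (must divide `C`); default 1.
#' @return A `token_grid` of identical shape; attribute `"weights"` holds the
#'   per-token attention weight matrices (rows sum to 1).
#' @export
token_attention <- function(t, p, heads = 1L) {
  stopifnot(inherits(t, "token_grid"))
  C <- t$C
  for (nm in c("wq", "wk", "wv")) {
    if (!all(dim(p[[nm]]) == c(C, C))) {
      stop("projection ", nm, " must be ", C, " x ", C, ", got ",
           paste(dim(p[[nm]]), collapse = " x "))
    }
  }
  if (C %% heads != 0L) stop("heads must divide the channel count")
  out <- t
  wts <- vector("list", length(t$tokens))
  for (k in seq_along(t$tokens)) {
    tok <- t$tokens[[k]]
    X <- matrix(tok, t$th * t$tw, C)
    a <- attn_one_fwd(X, p, heads)
    out$tokens[[k]] <- array(a$Y, dim = dim(tok))
    wts[[k]] <- a$cache$A
  }
  attr(out, "weights") <- wts
  out
}

# ---------------------------------------------------------------------------
# Layer normalization over channels (one statistic per pixel row).

ln_fwd <- function(X, p, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2, p$gamma, `*`)
  Y <- sweep(Y, 2, p$beta, `+`)
  list(Y = Y, cache = list(xhat = xhat, inv = inv, gamma = p$gamma))
}

ln_bwd <- function(dY, cache) {
  C <- ncol(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2, cache$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

#' Parameters for a tokenized-attention block
#'
#' Linear embedding (`C -> C`), layer norm, Q/K/V projections, and an output
#' projection.  The output projection is zero-initialized so that at
#' initialization the block's residual branch contributes nothing.
#'
#' @param C Channel count.
#' @param seed Optional seed.
#' @return Nested parameter list.
#' @export
tokatt_params <- function(C, seed = NULL) {
  make <- function() list(
    we = init_linear_w(C, C), be = numeric(C),
    ln = list(gamma = rep(1, C), beta = numeric(C)),
    wq = init_linear_w(C, C), wk = init_linear_w(C, C), wv = init_linear_w(C, C),
    wo = matrix(0, C, C), bo = numeric(C))
  if (is.null(seed)) make() else with_seed(seed, make())
}

# Batched TokAtt forward on (H, W, C, N); caches everything for backprop.
tokatt_b_fwd <- function(x, S, p, heads = 1L, residual = TRUE) {
  x <- as_t4(x); d <- dim(x)
  S <- as.integer(S)
  if (d[1] %% S != 0L || d[2] %% S != 0L) {
    stop(sprintf("S = %d does not divide the feature map: H = %d, W = %d", S, d[1], d[2]))
  }
  th <- d[1] %/% S; tw <- d[2] %/% S; C <- d[3]; N <- d[4]
  y <- array(0, dim = d)
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    Xm <- matrix(x[, , , n], d[1] * d[2], C)
    E <- sweep(Xm %*% p$we, 2, p$be, `+`)
    ln <- ln_fwd(E, p$ln)
    Earr <- array(ln$Y, dim = c(d[1], d[2], C))
    O <- matrix(0, d[1] * d[2], C)
    tcaches <- vector("list", S * S)
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        rows <- (i - 1L) * th + seq_len(th); cols <- (j - 1L) * tw + seq_len(tw)
        Xt <- matrix(Earr[rows, cols, , drop = FALSE], th * tw, C)
        a <- attn_one_fwd(Xt, p, heads)
        # scatter the token's rows back to their pixel positions
        pix <- as.vector(outer(rows, (cols - 1L) * d[1], `+`))
        O[pix, ] <- a$Y
        tcaches[[(i - 1L) * S + j]] <- list(cache = a$cache, pix = pix)
      }
    }
    Yn <- sweep(O %*% p$wo, 2, p$bo, `+`)
    caches[[n]] <- list(Xm = Xm, ln = ln$cache, tok = tcaches, O = O)
    y[, , , n] <- array(Yn, dim = c(d[1], d[2], C))
  }
  if (residual) y <- y + x
  list(y = y, cache = list(caches = caches, d = d, S = S, th = th, tw = tw,
                           heads = heads, residual = residual, p = p))
}

tokatt_b_bwd <- function(dy, cache) {
  d <- cache$d; C <- d[3]; N <- d[4]; p <- cache$p
  g <- list(we = matrix(0, C, C), be = numeric(C),
            ln = list(gamma = numeric(C), beta = numeric(C)),
            wq = matrix(0, C, C), wk = matrix(0, C, C), wv = matrix(0, C, C),
            wo = matrix(0, C, C), bo = numeric(C))
  dx <- array(0, dim = d)
  for (n in seq_len(N)) {
    cc <- cache$caches[[n]]
    dYn <- matrix(dy[, , , n], d[1] * d[2], C)
    g$wo <- g$wo + crossprod(cc$O, dYn)
    g$bo <- g$bo + colSums(dYn)
    dO <- tcrossprod(dYn, p$wo)
    dE <- matrix(0, d[1] * d[2], C)
    for (k in seq_along(cc$tok)) {
      tk <- cc$tok[[k]]
      ab <- attn_one_bwd(dO[tk$pix, , drop = FALSE], tk$cache, p)
      dE[tk$pix, ] <- ab$dX
      g$wq <- g$wq + ab$dwq; g$wk <- g$wk + ab$dwk; g$wv <- g$wv + ab$dwv
    }
    lb <- ln_bwd(dE, cc$ln)
    g$ln$gamma <- g$ln$gamma + lb$grads$gamma
    g$ln$beta <- g$ln$beta + lb$grads$beta
    g$we <- g$we + crossprod(cc$Xm, lb$dX)
    g$be <- g$be + colSums(lb$dX)
    dXn <- tcrossprod(lb$dX, p$we)
    dx[, , , n] <- array(dXn, dim = d[1:3])
  }
  if (cache$residual) dx <- dx + dy
  list(dx = dx, grads = g)
}

#' Tokenized-attention block forward pass
#'
#' Linear embedding, layer norm, tokenization into an `S x S` grid,
#' scaled-dot-product attention within each token, reassembly, output
#' projection, and (by default) a residual skip adding the input.
#' Output shape equals input shape.  With `S = 1` the block performs a
#' single global self-attention over all pixels.
#'
#' @param x `H x W x C` feature map (batched 4-D arrays also accepted).
#' @param S Tokens per side; must divide `H` and `W`.
#' @param p Parameters from [tokatt_params()].
#' @param heads Attention heads (default 1).
#' @param residual Add the input back to the block output (default `TRUE`).
#' @return Feature map of the same shape as `x`.
#' @export
tokatt_forward <- function(x, S, p, heads = 1L, residual = TRUE) {
  out <- tokatt_b_fwd(x, S, p, heads, residual)$y
  if (length(dim(x)) == 3L) out <- out[, , , 1, drop = TRUE]
  out
}

# ---------------------------------------------------------------------------
# C2fCS: CSP-style split-transform-concat fusion (a C2f with one compact
# inverted bottleneck) followed by the TokAtt block.

#' Parameters for the attention-augmented fusion block
#'
#' @param cin,cout Channel counts; the hidden width is `cout / 2`.
#' @param seed Optional seed.
#' @return Nested parameter list.
#' @export
c2fcs_params <- function(cin, cout, seed = NULL) {
  h <- max(1L, cout %/% 2L)
  make <- function() list(
    h = h,
    cv1 = cbs_params(cin, 2L * h, 1L),
    cib_dw = dwconv_params(h, 3L), cib_bn1 = bn_params(h),
    cib_pw = cbs_params(h, h, 1L),
    cv2 = cbs_params(3L * h, cout, 1L),
    att = tokatt_params(cout))
  if (is.null(seed)) make() else with_seed(seed, make())
}

c2fcs_state <- function(p) {
  h <- p$h
  list(cv1 = bn_state(2L * h), cib_bn1 = bn_state(h), cib_pw = bn_state(h),
       cv2 = bn_state(length(p$cv2$bn$gamma)))
}

c2fcs_fwd <- function(x, p, s, S = 4L, heads = 1L, train = TRUE, use_att = TRUE) {
  h <- p$h
  c1 <- cbs_fwd(x, p$cv1, s$cv1, 1L, train)
  a <- c1$y[, , seq_len(h), , drop = FALSE]
  b <- c1$y[, , h + seq_len(h), , drop = FALSE]
  dwc <- dwconv_fwd(b, p$cib_dw, 1L)
  bn1 <- bn_fwd(dwc$y, p$cib_bn1, s$cib_bn1, train)
  ac1 <- silu_fwd(bn1$y)
  pw <- cbs_fwd(ac1$y, p$cib_pw, s$cib_pw, 1L, train)
  m <- b + pw$y
  cat1 <- concat_ch(a, b)
  cat2 <- concat_ch(cat1$y, m)
  c2 <- cbs_fwd(cat2$y, p$cv2, s$cv2, 1L, train)
  att <- if (use_att) tokatt_b_fwd(c2$y, S, p$att, heads, residual = TRUE) else NULL
  list(y = if (use_att) att$y else c2$y,
       s = list(cv1 = c1$state, cib_bn1 = bn1$state, cib_pw = pw$state, cv2 = c2$state),
       cache = list(c1 = c1$cache, dwc = dwc$cache, bn1 = bn1$cache, ac1 = ac1$cache,
                    pw = pw$cache, cat1 = cat1$cache, cat2 = cat2$cache,
                    c2 = c2$cache, att = if (use_att) att$cache else NULL, h = h))
}

c2fcs_bwd <- function(dy, cache) {
  h <- cache$h
  if (!is.null(cache$att)) {
    ab <- tokatt_b_bwd(dy, cache$att)
    datt <- ab$dx; att_g <- ab$grads
  } else {
    datt <- dy; att_g <- NULL
  }
  c2b <- cbs_bwd(datt, cache$c2)
  sp2 <- split_ch(c2b$dx, cache$cat2)
  dm <- sp2$db
  sp1 <- split_ch(sp2$da, cache$cat1)
  da <- sp1$da; db <- sp1$db
  pwb <- cbs_bwd(dm, cache$pw)
  a1b <- silu_bwd(pwb$dx, cache$ac1)
  b1b <- bn_bwd(a1b$dx, cache$bn1)
  dwb <- dwconv_bwd(b1b$dx, cache$dwc)
  db_total <- db + dm + dwb$dx
  dc1 <- array(0, dim = dim(cache$c1$ac$x))
  dc1[, , seq_len(h), ] <- da
  dc1[, , h + seq_len(h), ] <- db_total
  c1b <- cbs_bwd(dc1, cache$c1)
  list(dx = c1b$dx,
       grads = c(list(cv1 = c1b$grads, cib_dw = dwb$grads, cib_bn1 = b1b$grads,
                      cib_pw = pwb$grads, cv2 = c2b$grads),
                 if (!is.null(att_g)) list(att = att_g)))
}

#' Attention-augmented CSP fusion block forward pass
#'
#' A split-transform-concat fusion block (1x1 expansion, one compact
#' inverted bottleneck on half of the channels, concatenation, 1x1 fusion)
#' whose output passes through the tokenized-attention block.  Because the
#' attention block's output projection is zero-initialized, a freshly built
#' block reproduces the plain fusion output exactly.
#'
#' @param x `H x W x C` feature map (batched arrays accepted).
#' @param p Parameters from [c2fcs_params()].
#' @param S Tokens per side for the attention stage (default 4).
#' @param heads Attention heads (default 1).
#' @return Feature map `H x W x cout`.
#' @export
c2fcs_forward <- function(x, p, S = 4L, heads = 1L) {
  x4 <- as_t4(x)
  if (dim(x4)[3] != dim(p$cv1$conv$w)[3]) {
    stop("channel mismatch: input has ", dim(x4)[3], " channels, block expects ",
         dim(p$cv1$conv$w)[3])
  }
  out <- c2fcs_fwd(x4, p, c2fcs_state(p), S, heads, train = TRUE)$y
  if (length(dim(x)) == 3L) out <- out[, , , 1, drop = TRUE]
  out
}
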