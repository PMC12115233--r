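# Internal differentiable layers. Tensors are 4-D arrays dim = c(H, W, C, N).
# Every *_fwd returns list(y, cache); every *_bwd takes (dy, cache) and
# returns list(dx = ..., grads = list(...)) with grads mirroring the params.

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature maps must be arrays, got a plain vector")
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
  } else if (length(d) != 4L) {
    stop("expected an H x W x C (x N) array, got ", length(d), " dims")
  }
  x
}

# --- broadcast / reduce over the channel axis ------------------------------

bcast_ch <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

reduce_ch <- function(x, d, f = rowSums) {
  m <- matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), d[3], d[4])
  if (identical(f, rowSums)) rowSums(m) else f(m)
}

# --- parameter initializers -------------------------------------------------

init_conv_w <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  bound <- sqrt(6 / fan_in)      # Kaiming-uniform, gain sqrt(2)
  array(runif(kh * kw * cin * cout, -bound, bound), dim = c(kh, kw, cin, cout))
}

init_linear_w <- function(cin, cout) {
  bound <- sqrt(6 / (cin + cout)) # Xavier-uniform
  matrix(runif(cin * cout, -bound, bound), cin, cout)
}

conv_params <- function(cin, cout, k = 3L) {
  list(w = init_conv_w(k, k, cin, cout), b = numeric(cout))
}

dwconv_params <- function(c, k = 3L) {
  list(w = array(runif(k * k * c, -sqrt(6 / (k * k)), sqrt(6 / (k * k))),
                 dim = c(k, k, c)),
       b = numeric(c))
}

bn_params <- function(c) list(gamma = rep(1, c), beta = numeric(c))

bn_state <- function(c) list(mean = numeric(c), var = rep(1, c), n = 0L)

# --- convolution ------------------------------------------------------------

conv_fwd <- function(x, p, stride = 1L, pad = NULL) {
  x <- as_t4(x)
  k <- dim(p$w)[1:2]
  if (is.null(pad)) pad <- k %/% 2L
  y <- .conv2d_fwd(x, p$w, p$b, as.integer(stride), as.integer(pad[1]), as.integer(pad[2]))
  list(y = y, cache = list(x = x, p = p, stride = stride, pad = pad))
}

conv_bwd <- function(dy, cache, need_dx = TRUE) {
  g <- .conv2d_bwd(dy, cache$x, cache$p$w, as.integer(cache$stride),
                   as.integer(cache$pad[1]), as.integer(cache$pad[2]), need_dx)
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

dwconv_fwd <- function(x, p, stride = 1L, pad = NULL) {
  x <- as_t4(x)
  k <- dim(p$w)[1:2]
  if (is.null(pad)) pad <- k %/% 2L
  y <- .dwconv_fwd(x, p$w, p$b, as.integer(stride), as.integer(pad[1]), as.integer(pad[2]))
  list(y = y, cache = list(x = x, p = p, stride = stride, pad = pad))
}

dwconv_bwd <- function(dy, cache) {
  g <- .dwconv_bwd(dy, cache$x, cache$p$w, as.integer(cache$stride),
                   as.integer(cache$pad[1]), as.integer(cache$pad[2]))
  list(dx = g$dx, grads = list(w = g$dw, b = g$db))
}

# --- batch normalization ----------------------------------------------------
# Training mode uses batch statistics over (H, W, N) per channel and updates
# running estimates; eval mode uses the running estimates.

bn_fwd <- function(x, p, state, train = TRUE, momentum = 0.1, eps = 1e-5) {
  x <- as_t4(x); d <- dim(x)
  m <- d[1] * d[2] * d[4]
  if (train || state$n == 0L) {
    mu <- reduce_ch(x, d) / m
    m2 <- reduce_ch(x * x, d) / m
    v <- pmax(m2 - mu^2, 0)
    if (train) {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * v
      state$n <- state$n + 1L
    }
  } else {
    mu <- state$mean; v <- state$var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- .ch_affine(x, inv, -mu * inv)
  y <- .ch_affine(xhat, p$gamma, p$beta)
  list(y = y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = p$gamma, d = d, m = m))
}

bn_bwd <- function(dy, cache) {
  d <- cache$d; m <- cache$m
  dgamma <- reduce_ch(dy * cache$xhat, d)
  dbeta <- reduce_ch(dy, d)
  # dx = (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) * inv, with
  # dxhat = dy * gamma; the means fold into per-channel affine coefficients
  dx <- .ch_affine2(dy, cache$xhat,
                    cache$gamma * cache$inv,
                    -(dgamma * cache$gamma / m) * cache$inv,
                    -(dbeta * cache$gamma / m) * cache$inv)
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# --- SiLU -------------------------------------------------------------------

silu_fwd <- function(x) {
  r <- .silu_fwd_cpp(x)
  list(y = r$y, cache = list(x = x, s = r$s))
}

silu_bwd <- function(dy, cache) {
  list(dx = .silu_bwd_cpp(dy, cache$x, cache$s))
}

# --- fused conv + BN + SiLU, the workhorse unit -----------------------------

cbs_params <- function(cin, cout, k = 3L) {
  list(conv = conv_params(cin, cout, k), bn = bn_params(cout))
}

cbs_fwd <- function(x, p, state, stride = 1L, train = TRUE) {
  cv <- conv_fwd(x, p$conv, stride)
  bn <- bn_fwd(cv$y, p$bn, state, train)
  ac <- silu_fwd(bn$y)
  list(y = ac$y, state = bn$state,
       cache = list(cv = cv$cache, bn = bn$cache, ac = ac$cache))
}

cbs_bwd <- function(dy, cache) {
  d1 <- silu_bwd(dy, cache$ac)
  d2 <- bn_bwd(d1$dx, cache$bn)
  d3 <- conv_bwd(d2$dx, cache$cv)
  list(dx = d3$dx, grads = list(conv = d3$grads, bn = d2$grads))
}

# --- nearest-neighbour 2x upsampling ---------------------------------------

upsample2_fwd <- function(x) {
  x <- as_t4(x); d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  list(y = y, cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache
  ro <- seq(1, 2 * d[1], by = 2); co <- seq(1, 2 * d[2], by = 2)
  dx <- dy[ro, co, , , drop = FALSE] + dy[ro + 1, co, , , drop = FALSE] +
    dy[ro, co + 1, , , drop = FALSE] + dy[ro + 1, co + 1, , , drop = FALSE]
  list(dx = dx)
}

# --- channel concatenation --------------------------------------------------

concat_ch <- function(a, b) {
  a <- as_t4(a); b <- as_t4(b)
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  list(y = y, cache = list(ca = da[3], cb = db[3]))
}

split_ch <- function(dy, cache) {
  list(da = dy[, , seq_len(cache$ca), , drop = FALSE],
       db = dy[, , cache$ca + seq_len(cache$cb), , drop = FALSE])
}
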