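# Array convolution engine.
#
# Internal activation layout is (H, W, N, C): channels last, so per-channel
# batch-norm statistics, global pooling and the channel contraction of a
# convolution all operate on contiguous column-major reshapes without any
# transposition. A k x k convolution is computed as k^2 shifted
# (H*W*N x Cin) %*% (Cin x Cout) BLAS products accumulated into the output;
# the backward pass mirrors this with scatter-adds into the padded gradient.
# The public batch contract is (N, C, H, W); conversion happens once per
# batch at the network boundary.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

nchw_to_hwcn <- function(x) aperm(x, c(3L, 4L, 1L, 2L))   # -> (H, W, N, C)
hwcn_to_nchw <- function(x) aperm(x, c(3L, 4L, 1L, 2L))

conv_out_dim <- function(n, kernel, stride, padding) {
  out <- (n + 2L * padding - kernel) %/% stride + 1L
  if (out < 1L)
    stop("convolution output size < 1 (input ", n, ", kernel ", kernel,
         ", stride ", stride, ", padding ", padding, ")")
  out
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[(p + 1L):(p + d[1L]), (p + 1L):(p + d[2L]), , ] <- x
  xp
}

crop_pad <- function(xp, p, h, w) {
  if (p == 0L) return(xp)
  xp[(p + 1L):(p + h), (p + 1L):(p + w), , , drop = FALSE]
}

# dense convolution; weights (k, k, Cin, Cout), x (H, W, N, Cin)
conv2d_forward <- function(x, w, b = NULL, stride = 1L, padding = 0L) {
  d <- dim(x); k <- dim(w)[1L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  if (d[4L] != cin)
    stop("conv2d: input has ", d[4L], " channels, weights expect ", cin)
  ho <- conv_out_dim(d[1L], k, stride, padding)
  wo <- conv_out_dim(d[2L], k, stride, padding)
  xp <- pad_hw(x, padding)
  m <- ho * wo * d[3L]
  if (k == 1L && stride == 1L && padding == 0L) {
    y <- matrix(x, m, cin) %*% matrix(w, cin, cout)   # pointwise fast path
  } else {
    y <- matrix(0, m, cout)
    for (i in seq_len(k)) {
      ri <- seq.int(i, by = stride, length.out = ho)
      for (j in seq_len(k)) {
        cj <- seq.int(j, by = stride, length.out = wo)
        xs <- matrix(xp[ri, cj, , ], m, cin)
        y <- y + xs %*% matrix(w[i, j, , ], cin, cout)
      }
    }
  }
  if (!is.null(b)) y <- y + rep(b, each = m)
  list(out = array(y, dim = c(ho, wo, d[3L], cout)),
       cache = list(xp = xp, dims = d, k = k, stride = stride,
                    padding = padding, ho = ho, wo = wo))
}

conv2d_backward <- function(dy, w, cache) {
  d <- cache$dims; k <- cache$k; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  ho <- cache$ho; wo <- cache$wo
  m <- ho * wo * d[3L]
  dym <- matrix(dy, m, cout)
  if (k == 1L && cache$stride == 1L && cache$padding == 0L) {
    dw <- array(crossprod(matrix(cache$xp, m, cin), dym), dim = dim(w))
    dx <- array(tcrossprod(dym, matrix(w, cin, cout)), dim = d)
    return(list(dx = dx, dw = dw, db = colSums(dym)))
  }
  dw <- array(0, dim = dim(w))
  dxp <- array(0, dim = dim(cache$xp))
  for (i in seq_len(k)) {
    ri <- seq.int(i, by = cache$stride, length.out = ho)
    for (j in seq_len(k)) {
      cj <- seq.int(j, by = cache$stride, length.out = wo)
      xs <- matrix(cache$xp[ri, cj, , ], m, cin)
      dw[i, j, , ] <- crossprod(xs, dym)
      dxs <- tcrossprod(dym, matrix(w[i, j, , ], cin, cout))
      dxp[ri, cj, , ] <- dxp[ri, cj, , , drop = FALSE] +
        array(dxs, dim = c(ho, wo, d[3L], cin))
    }
  }
  list(dx = crop_pad(dxp, cache$padding, d[1L], d[2L]),
       dw = dw, db = colSums(dym))
}

# depthwise convolution; weights (k, k, C); compiled kernel
depthwise_forward <- function(x, w, b = NULL, stride = 1L, padding = 0L) {
  d <- dim(x); k <- dim(w)[1L]; ch <- dim(w)[3L]
  if (d[4L] != ch)
    stop("depthwise conv: input has ", d[4L], " channels, weights expect ", ch)
  conv_out_dim(d[1L], k, stride, padding)   # validates geometry
  y <- .dw_fwd(x, d, w, k, as.integer(stride), as.integer(padding))
  if (!is.null(b)) y <- y + rep(b, each = prod(dim(y)[1:3]))
  list(out = y, cache = list(x = x, k = k, stride = as.integer(stride),
                             padding = as.integer(padding)))
}

depthwise_backward <- function(dy, w, cache) {
  r <- .dw_bwd(dy, cache$x, dim(cache$x), w, cache$k, cache$stride,
               cache$padding)
  dd <- dim(dy)
  list(dx = r$dx, dw = r$dw,
       db = colSums(matrix(dy, dd[1L] * dd[2L] * dd[3L], dd[4L])))
}

# batch normalization over (H, W, N) per channel
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training = TRUE) {
  d <- dim(x)
  m <- d[1L] * d[2L] * d[3L]
  xm <- matrix(x, m, d[4L])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    running_mean <- (1 - BN_MOMENTUM) * running_mean + BN_MOMENTUM * mu
    # unbiased variance for the running estimate, as is conventional
    vu <- if (m > 1L) v * m / (m - 1L) else v
    running_var <- (1 - BN_MOMENTUM) * running_var + BN_MOMENTUM * vu
  } else {
    mu <- running_mean
    v <- running_var
    xc <- xm - rep(mu, each = m)
  }
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(inv_sd, each = m)
  ym <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  list(out = array(ym, dim = d),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dims = d,
                    m = m, training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dy, cache) {
  d <- cache$dims; m <- cache$m
  dym <- matrix(dy, m, d[4L])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(cache$gamma, each = m)
  if (cache$training) {
    t1 <- dxhat - rep(colMeans(dxhat), each = m)
    t2 <- cache$xhat * rep(colMeans(dxhat * cache$xhat), each = m)
    dxm <- (t1 - t2) * rep(cache$inv_sd, each = m)
  } else {
    dxm <- dxhat * rep(cache$inv_sd, each = m)
  }
  list(dx = array(dxm, dim = d), dgamma = dgamma, dbeta = dbeta)
}

# global average pooling (H, W, N, C) -> (N, C)
gap_forward <- function(x) {
  d <- dim(x)
  if (d[1L] < 1L || d[2L] < 1L) stop("global pooling: empty spatial extent")
  y <- colMeans(array(x, dim = c(d[1L] * d[2L], d[3L], d[4L])))
  list(out = matrix(y, d[3L], d[4L]), cache = d)
}

gap_backward <- function(dy, d) {
  hw <- d[1L] * d[2L]
  array(rep(as.vector(dy) / hw, each = hw), dim = d)
}

linear_forward <- function(x, w, b) {
  list(out = x %*% t(w) + rep(b, each = nrow(x)), cache = x)
}

linear_backward <- function(dy, w, cache) {
  list(dx = dy %*% w, dw = crossprod(dy, cache), db = colSums(dy))
}
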