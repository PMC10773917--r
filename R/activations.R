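#' Swish activation
#'
#' Computes the swish nonlinearity \eqn{x \cdot \sigma(\beta x)} elementwise,
#' where \eqn{\sigma} is the logistic function. \code{beta} controls the slope
#' of the gate: small values approach a scaled linear function, large values
#' approach ReLU.
#'
#' @param x numeric array (any shape); must be finite.
#' @param beta positive gate slope (dimensionless). Default 1.
#' @return array of the same shape as \code{x}.
#' @examples
#' swish(1)        # 0.7310586
#' swish(c(-2, 0, 2))
#' @export
swish <- function(x, beta = 1) {
  check_finite(x, "swish")
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  x * stats::plogis(beta * x)
}

#' Clipped swish (swish6) activation
#'
#' swish whose output is clamped at 6 for inputs at or above 6, analogous to
#' ReLU6's clipping of ReLU: the unbounded growth of swish for large inputs can
#' destabilise training, so the output is fixed at the constant 6 on the upper
#' branch.
#'
#' Two clamp dialects are provided. The default, piecewise form returns
#' \code{swish(x)} for \code{x < 6} and exactly 6 for \code{x >= 6}; for
#' \code{beta = 1} this has a small upward jump of \eqn{6 - 6\sigma(6)} at
#' \code{x = 6}. Setting \code{continuous = TRUE} instead returns
#' \code{pmin(swish(x), 6)}, which is continuous everywhere.
#'
#' @inheritParams swish
#' @param continuous use the continuous \code{min(swish(x), 6)} form instead of
#'   the literal piecewise clamp. Default \code{FALSE}.
#' @return array of the same shape as \code{x}; never exceeds 6.
#' @examples
#' swish6(10)   # 6
#' swish6(3)    # 2.857722, identical to swish(3)
#' @export
swish6 <- function(x, beta = 1, continuous = FALSE) {
  y <- swish(x, beta)
  if (continuous) return(pmin(y, 6))
  y[x >= 6] <- 6
  y
}

# derivative of swish6 w.r.t. x (piecewise form: zero on the clamped branch)
swish6_grad <- function(x, beta = 1) {
  s <- stats::plogis(beta * x)
  g <- s + x * beta * s * (1 - s)
  g[x >= 6] <- 0
  g
}

#' Numerically stable softmax
#'
#' Maps a vector of logits to a probability vector
#' \eqn{p_i = e^{z_i} / \sum_j e^{z_j}}, computed after subtracting
#' \code{max(z)} so that large logits cannot overflow. For a matrix,
#' \code{softmax_rows} applies the map to each row independently.
#'
#' @param z finite numeric vector of length >= 1.
#' @return probability vector of the same length; entries in [0,1], summing
#'   to 1.
#' @examples
#' softmax(c(0, log(2)))   # 1/3, 2/3
#' sum(softmax(rnorm(7)))  # 1
#' @export
softmax <- function(z) {
  if (length(z) == 0L) stop("softmax: empty logit vector")
  check_finite(z, "softmax")
  e <- exp(z - max(z))
  e / sum(e)
}

#' @rdname softmax
#' @param logits numeric matrix, one logit vector per row.
#' @export
softmax_rows <- function(logits) {
  if (!is.matrix(logits) || ncol(logits) == 0L)
    stop("softmax_rows: need a non-empty numeric matrix")
  check_finite(logits, "softmax_rows")
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

pool_2x2 <- function(grid, fun) {
  if (!is.matrix(grid)) stop("pooling expects a 2-D array")
  h <- nrow(grid); w <- ncol(grid)
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("pooling requires even height and width (stride-2, no padding); got ",
         h, "x", w)
  # reshape so each non-overlapping 2x2 window becomes one column
  a <- array(grid, dim = c(2L, h %/% 2L, w))
  a <- aperm(a, c(1L, 3L, 2L))                    # (2, w, h/2)
  a <- array(a, dim = c(2L, 2L, w %/% 2L, h %/% 2L))
  out <- apply(a, c(4L, 3L), fun)                 # (h/2, w/2)
  matrix(out, nrow = h %/% 2L, ncol = w %/% 2L)
}

#' Non-overlapping 2x2 pooling
#'
#' Downsamples a 2-D feature map by taking the maximum
#' (\code{max_pool_2x2}) or arithmetic mean (\code{avg_pool_2x2}) of each
#' non-overlapping 2x2 window, stride fixed at 2. Both dimensions must be
#' even; no padding dialect is defined.
#'
#' @param grid numeric matrix with even numbers of rows and columns.
#' @return matrix of half the height and width.
#' @examples
#' m <- matrix(c(1, 5, 2, 10,
#'               3, 4, 8, 6,
#'               9, 1, 2, 7,
#'               0, 2, 3, 1), 4, 4, byrow = TRUE)
#' max_pool_2x2(m)
#' avg_pool_2x2(matrix(c(2, 3, 2, 5), 2, 2))  # mean of the window: 3
#' @export
max_pool_2x2 <- function(grid) pool_2x2(grid, max)

#' @rdname max_pool_2x2
#' @export
avg_pool_2x2 <- function(grid) pool_2x2(grid, mean)

#' Global average pooling
#'
#' Collapses each channel of a C x H x W feature stack to the mean over all
#' H*W spatial positions, yielding the per-channel feature vector consumed by
#' the linear classifier head.
#'
#' @param features numeric array of dimension (C, H, W) with H, W >= 1.
#' @return numeric vector of length C.
#' @examples
#' f <- array(seq_len(2 * 2 * 2), dim = c(2, 2, 2))
#' global_avg_pool(f)
#' @export
global_avg_pool <- function(features) {
  d <- dim(features)
  if (is.null(d) || length(d) != 3L)
    stop("global_avg_pool expects a rank-3 array (C, H, W)")
  if (d[2L] < 1L || d[3L] < 1L) stop("global_avg_pool: empty spatial extent")
  apply(features, 1L, mean)
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, ": input must be finite numeric")
  invisible(TRUE)
}
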