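# R-side primitives of the conv-net engine. The convolution and pooling
# kernels live in src/nn_ops.cpp; everything here is plain array math so the
# whole computation graph stays finite-difference checkable.

as_batch4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) oct_abort("expected an array input")
  if (length(d) == 2) {
    dim(x) <- c(d, 1L, 1L)
  } else if (length(d) == 3) {
    dim(x) <- c(d[1], d[2], 1L, d[3])
  } else if (length(d) != 4) {
    oct_abort("expected a (H, W, C, N) array")
  }
  x
}

conv_fwd <- function(x, w, b, stride = 1L, pad = 1L) {
  nn_conv_fwd(x, w, b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, dy, stride = 1L, pad = 1L) {
  nn_conv_bwd(x, w, dy, as.integer(stride), as.integer(pad))
}

maxpool_fwd <- function(x, k = 2L, stride = 2L) {
  nn_maxpool_fwd(x, as.integer(k), as.integer(stride))
}

maxpool_bwd <- function(dy, idx, xdim) {
  nn_maxpool_bwd(dy, idx, as.integer(xdim))
}

lrelu <- function(x, slope) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * x[neg]
  y
}

lrelu_grad <- function(x, slope) {
  g <- array(1, dim(x))
  g[x < 0] <- slope
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

global_avg_pool <- function(x) {
  d <- dim(x)                      # (H, W, C, N)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[3], d[4])            # C x N
}

global_avg_pool_bwd <- function(dg, xdim) {
  # spread the gradient uniformly over the spatial positions
  array(rep(dg, each = xdim[1] * xdim[2]) / (xdim[1] * xdim[2]), dim = xdim)
}

# softmax + categorical cross-entropy; labels as one-hot (K x N)
softmax_probs <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

crossentropy_loss <- function(probs, onehot) {
  n <- ncol(probs)
  -sum(onehot * log(pmax(probs, 1e-12))) / n
}

crossentropy_grad <- function(probs, onehot) {
  (probs - onehot) / ncol(probs)
}

one_hot <- function(labels, levels = GRADE_LEVELS) {
  labels <- as.character(labels)
  if (!all(labels %in% levels)) oct_abort("unknown class label in `labels`")
  m <- matrix(0, length(levels), length(labels),
              dimnames = list(levels, NULL))
  m[cbind(match(labels, levels), seq_along(labels))] <- 1
  m
}
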