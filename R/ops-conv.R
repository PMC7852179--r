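# Convolutional primitives on position-major feature maps.
#
# A feature map on an H x W grid is stored as an N x C matrix with N = H*W
# and position index p = h + (w-1)*H (column-major grid scan, matching how R
# vectorizes an H x W matrix).  3x3 convolutions are evaluated by im2col:
# gather the nine shifted copies of the (zero-padded) map into an
# N x (9*C_in) matrix and multiply by a (9*C_in) x C_out weight matrix.

# im2col expansion: (B*N) x C stacked maps -> (B*N) x (9*C), zero padding,
# columns ordered offset-fastest within each input channel (see src/).
im2col3 <- function(x, H, W, B = 1L) .im2col3_cpp(x, H, W, B)

# The input cotangent of a 3x3 convolution is itself a 3x3 convolution of
# the output cotangent with the spatially flipped, channel-transposed
# kernel; rearrange w ((9*Cin) x Cout, offset-fastest) accordingly.
flip_kernel <- function(w, cin) {
  cout <- ncol(w)
  aw <- array(w, c(9L, cin, cout))
  matrix(aperm(aw[9:1, , , drop = FALSE], c(1L, 3L, 2L)), 9L * cout, cin)
}

# 3x3 convolution, stride 1, zero padding, applied per sample to B stacked
# maps; w is (9*C_in) x C_out with rows ordered offset-fastest within each
# input channel; b is a 1 x C_out matrix or NULL.
tp_conv3 <- function(tp, x, w, b, H, W, B = 1L) {
  xc <- im2col3(x$v, H, W, B)
  y <- xc %*% w$v
  if (!is.null(b)) y <- sweep_add_rowvec(y, b$v)
  if (!tp$grad) return(tp_node(tp, y))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  cin <- ncol(x$v)
  tp_node(tp, y, parents, function(g, nd) {
    gw <- crossprod(xc, g)
    gx <- im2col3(g, H, W, B) %*% flip_kernel(nd$parents[[2]]$v, cin)
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(g))
  })
}

# 1x1 convolution = plain channel mixing.
tp_conv1 <- function(tp, x, w, b = NULL) {
  y <- x$v %*% w$v
  if (!is.null(b)) y <- sweep_add_rowvec(y, b$v)
  if (!tp$grad) return(tp_node(tp, y))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tp_node(tp, y, parents, function(g, nd) {
    gx <- g %*% t(nd$parents[[2]]$v)
    gw <- crossprod(nd$parents[[1]]$v, g)
    if (is.null(b)) list(gx, gw) else list(gx, gw, colSums(g))
  })
}

sweep_add_rowvec <- function(m, v) m + rep(v, each = nrow(m))

.pool_cache <- new.env(parent = emptyenv())

pool2_indices <- function(H, W, B = 1L) {
  key <- paste0(H, "x", W, "x", B)
  hit <- .pool_cache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ho <- rep(seq_len(Ho), times = Wo)
  wo <- rep(seq_len(Wo), each = Ho)
  idx1 <- matrix(0L, Ho * Wo, 4L)
  o <- 0L
  for (dw in 0L:1L) for (dh in 0L:1L) {
    o <- o + 1L
    idx1[, o] <- (2L * ho - 1L + dh) + (2L * wo - 2L + dw) * H
  }
  idx <- do.call(rbind, lapply(seq_len(B) - 1L, function(b) idx1 + b * H * W))
  res <- list(idx = idx, Ho = Ho, Wo = Wo)
  .pool_cache[[key]] <- res
  res
}

# 2x2 average pooling (H, W even), per sample over B stacked maps.
tp_avgpool2 <- function(tp, x, H, W, B = 1L) {
  pi <- pool2_indices(H, W, B)
  v <- 0.25 * (x$v[pi$idx[, 1], , drop = FALSE] + x$v[pi$idx[, 2], , drop = FALSE] +
               x$v[pi$idx[, 3], , drop = FALSE] + x$v[pi$idx[, 4], , drop = FALSE])
  if (!tp$grad) return(tp_node(tp, v))
  tp_node(tp, v, list(x), function(g, nd) {
    gx <- nd$parents[[1]]$v
    gx[] <- 0
    for (o in 1:4) gx[pi$idx[, o], ] <- gx[pi$idx[, o], ] + 0.25 * g
    list(gx)
  })
}

# Batch normalization over rows (all positions of all samples in the batch),
# per channel, training mode.  gamma/beta are length-C vectors (as 1 x C).
# Batch statistics are attached so the caller can update running buffers.
tp_bn <- function(tp, x, gamma, beta, eps = 1e-5) {
  m <- colMeans(x$v)
  xc <- sweep_add_rowvec(x$v, -m)
  vvar <- colMeans(xc * xc)
  istd <- 1 / sqrt(vvar + eps)
  xhat <- xc * rep(istd, each = nrow(xc))
  y <- xhat * rep(gamma$v, each = nrow(xc))
  y <- sweep_add_rowvec(y, beta$v)
  nd <- tp_node(tp, y, list(x, gamma, beta), function(g, nd) {
    n <- nrow(g)
    gg <- g * rep(gamma$v, each = n)          # dL/dxhat
    gmean <- colMeans(gg)
    gxhat_mean <- colMeans(gg * xhat)
    gx <- (gg - rep(gmean, each = n) - xhat * rep(gxhat_mean, each = n)) *
      rep(istd, each = n)
    list(gx, colSums(g * xhat), colSums(g))
  })
  attr(nd, "batch_mean") <- m
  attr(nd, "batch_var") <- vvar
  nd
}

# Inference-mode batch norm from stored running statistics (affine only).
tp_bn_eval <- function(tp, x, gamma, beta, rmean, rvar, eps = 1e-5) {
  istd <- 1 / sqrt(rvar + eps)
  a <- gamma$v * istd
  b <- beta$v - gamma$v * rmean * istd
  y <- sweep_add_rowvec(x$v * rep(a, each = nrow(x$v)), b)
  if (!tp$grad) return(tp_node(tp, y))
  tp_node(tp, y, list(x), function(g, nd) list(g * rep(a, each = nrow(g))))
}
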