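# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Every differentiable quantity is a node (an environment) holding its value
# `v`, accumulated gradient `g`, parent nodes and a pullback closure.  Nodes
# are appended in forward order, so reverse iteration is a valid topological
# order for backpropagation.  Operations are coarse (whole convolutions,
# grouped attention, batch norm), which keeps the interpretive overhead per
# tape node negligible next to the BLAS work inside it.

# grad = FALSE builds a value-only tape: no pullbacks are recorded and no
# intermediates are retained, which keeps inference memory flat.
tape_new <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$grad <- grad
  tp
}

tp_node <- function(tp, value, parents = list(), backfun = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$parents <- parents
  nd$backfun <- backfun
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- nd
  tp$n <- n
  nd
}

tp_const <- function(tp, x) tp_node(tp, x)

# Leaf node for a trainable parameter; gradient is read off nd$g afterwards.
tp_leaf <- function(tp, x) tp_node(tp, x)

.acc <- function(nd, g) {
  if (is.null(g)) return(invisible(NULL))
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(NULL)
}

# Backpropagate from scalar root (seed gradient 1).
tape_backward <- function(tp, root) {
  root$g <- 1
  for (i in seq(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$g) || is.null(nd$backfun)) next
    gs <- nd$backfun(nd$g, nd)
    ps <- nd$parents
    for (k in seq_along(ps)) .acc(ps[[k]], gs[[k]])
  }
  invisible(NULL)
}

## ---- elementwise and linear-algebra primitives ----

tp_add <- function(tp, a, b) {
  if (!tp$grad) return(tp_node(tp, a$v + b$v))
  tp_node(tp, a$v + b$v, list(a, b), function(g, nd) {
    ga <- if (length(nd$parents[[1]]$v) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(nd$parents[[2]]$v) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

tp_sub <- function(tp, a, b) {
  if (!tp$grad) return(tp_node(tp, a$v - b$v))
  tp_node(tp, a$v - b$v, list(a, b), function(g, nd) {
    gb <- if (length(nd$parents[[2]]$v) == 1L && length(g) > 1L) -sum(g) else -g
    list(g, gb)
  })
}

tp_mul <- function(tp, a, b) {
  av <- if (length(a$v) == 1L) as.vector(a$v) else a$v
  bv <- if (length(b$v) == 1L) as.vector(b$v) else b$v
  if (!tp$grad) return(tp_node(tp, av * bv))
  tp_node(tp, av * bv, list(a, b), function(g, nd) {
    ga <- g * bv
    gb <- g * av
    if (length(nd$parents[[1]]$v) == 1L && length(ga) > 1L) ga <- sum(ga)
    if (length(nd$parents[[2]]$v) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

# Multiply by an untracked constant.
tp_scale <- function(tp, a, s) {
  if (!tp$grad) return(tp_node(tp, a$v * s))
  tp_node(tp, a$v * s, list(a), function(g, nd) list(g * s))
}

tp_matmul <- function(tp, a, b) {
  tp_node(tp, a$v %*% b$v, list(a, b), function(g, nd) {
    list(g %*% t(nd$parents[[2]]$v), crossprod(nd$parents[[1]]$v, g))
  })
}

tp_relu <- function(tp, a) {
  v <- a$v
  v[v < 0] <- 0
  if (!tp$grad) return(tp_node(tp, v))
  tp_node(tp, v, list(a), function(g, nd) {
    g[nd$parents[[1]]$v <= 0] <- 0
    list(g)
  })
}

tp_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-a$v))
  if (!tp$grad) return(tp_node(tp, s))
  nd <- tp_node(tp, s, list(a), function(g, nd) list(g * nd$v * (1 - nd$v)))
  nd
}

tp_sum <- function(tp, a) {
  tp_node(tp, sum(a$v), list(a), function(g, nd) {
    gv <- nd$parents[[1]]$v
    gv[] <- g
    list(gv)
  })
}

# Column-concatenate matrices with equal row counts.
tp_cbind <- function(tp, xs) {
  ncols <- vapply(xs, function(x) ncol(x$v), 1L)
  if (!tp$grad) return(tp_node(tp, do.call(cbind, lapply(xs, function(x) x$v))))
  tp_node(tp, do.call(cbind, lapply(xs, function(x) x$v)), xs, function(g, nd) {
    out <- vector("list", length(ncols))
    at <- 0L
    for (k in seq_along(ncols)) {
      out[[k]] <- g[, at + seq_len(ncols[k]), drop = FALSE]
      at <- at + ncols[k]
    }
    out
  })
}

# Row-concatenate matrices with equal column counts (used to share batch
# statistics across the samples of a minibatch).
tp_rbind <- function(tp, xs) {
  nrows <- vapply(xs, function(x) nrow(x$v), 1L)
  if (!tp$grad) return(tp_node(tp, do.call(rbind, lapply(xs, function(x) x$v))))
  tp_node(tp, do.call(rbind, lapply(xs, function(x) x$v)), xs, function(g, nd) {
    out <- vector("list", length(nrows))
    at <- 0L
    for (k in seq_along(nrows)) {
      out[[k]] <- g[at + seq_len(nrows[k]), , drop = FALSE]
      at <- at + nrows[k]
    }
    out
  })
}

# Select rows by index (indices must be unique for the scatter-add pullback).
tp_rows <- function(tp, a, idx) {
  force(idx)
  if (!tp$grad) return(tp_node(tp, a$v[idx, , drop = FALSE]))
  tp_node(tp, a$v[idx, , drop = FALSE], list(a), function(g, nd) {
    gv <- nd$parents[[1]]$v
    gv[] <- 0
    gv[idx, ] <- g
    list(gv)
  })
}

## ---- loss primitives ----

# sum((a - b)^2); b may be a node or a plain constant matrix.
tp_frob2 <- function(tp, a, b) {
  if (is.environment(b)) {
    d <- a$v - b$v
    tp_node(tp, sum(d * d), list(a, b), function(g, nd) {
      d <- nd$parents[[1]]$v - nd$parents[[2]]$v
      list(g * 2 * d, -g * 2 * d)
    })
  } else {
    d <- a$v - b
    tp_node(tp, sum(d * d), list(a), function(g, nd) {
      list(g * 2 * (nd$parents[[1]]$v - b))
    })
  }
}

# Charbonnier penalty: sum over entries of sqrt((a-b)^2 + eps^2).
tp_charbonnier <- function(tp, a, b, eps = 1e-6) {
  bv <- if (is.environment(b)) b$v else b
  d <- a$v - bv
  r <- sqrt(d * d + eps * eps)
  tp_node(tp, sum(r), list(a), function(g, nd) {
    d <- nd$parents[[1]]$v - bv
    list(g * d / sqrt(d * d + eps * eps))
  })
}

# Gram matrix of a position-major feature map F (N x C): t(F) F / (C * N).
tp_gram <- function(tp, f) {
  nc <- ncol(f$v); nr <- nrow(f$v)
  sc <- 1 / (nc * nr)
  tp_node(tp, crossprod(f$v) * sc, list(f), function(g, nd) {
    list(nd$parents[[1]]$v %*% ((g + t(g)) * sc))
  })
}
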