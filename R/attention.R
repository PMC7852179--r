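# Attention-aware layer (AAL): scaled dot-product self-attention factorized
# into interlaced long-range / short-range block attention, optionally
# recursively for two levels.  A dense O(N^2) oracle and operation-count
# accounting accompany the fast grouped path.
#
# Conventions used throughout:
#  * user-facing feature maps are channel-major C x N matrices, matching the
#    usual matrix statement of self-attention (X in R^{C x N});
#  * positions on the H x W grid are numbered column-major, p = h + (w-1)*H,
#    i.e. scanning down columns, matching R's vectorization of an H x W
#    matrix;
#  * the affinity matrix A is normalized so that every column sums to one:
#    column j holds the weights with which output position j aggregates all
#    key positions, making Z = (W_h X) A a convex aggregation per output.

#' Attention configuration
#'
#' Describes the channel reduction and the spatial partition geometry of the
#' attention-aware layer.  Level 1 splits the `H x W` grid into
#' `P_h x P_w` strided (long-range) groups of `Q_h x Q_w` positions;
#' level 2 partitions each level-1 group's `Q_h x Q_w` grid the same way.
#'
#' @param k channel-reduction factor; attention operates on `C/k` channels.
#' @param level1 integer vector `c(P_h, P_w, Q_h, Q_w)`; requires
#'   `H == P_h * Q_h` and `W == P_w * Q_w` for the maps it is applied to.
#' @param level2 integer vector `c(P'_h, P'_w, Q'_h, Q'_w)` partitioning the
#'   level-1 group grid; requires `Q_h == P'_h * Q'_h`, `Q_w == P'_w * Q'_w`.
#'   Ignored when `levels = 1`.
#' @param levels depth of the decomposition, 1 (interlaced long/short) or
#'   2 (long-range groups are themselves decomposed before the final
#'   short-range pass).
#' @param gate_init initial value of the residual gates `gamma` (one scalar
#'   per attention application); 0 makes the layer the identity map at
#'   initialization.
#' @return an object of class `"attention_config"`.
#' @export
attention_config <- function(k = 2L, level1 = c(2L, 2L, 4L, 4L),
                             level2 = c(2L, 2L, 2L, 2L),
                             levels = 2L, gate_init = 0) {
  stopifnot(length(level1) == 4L, all(level1 >= 1L),
            levels %in% c(1L, 2L), k >= 1L)
  if (levels == 2L) {
    stopifnot(length(level2) == 4L, all(level2 >= 1L))
    if (level1[3L] != level2[1L] * level2[3L] ||
        level1[4L] != level2[2L] * level2[4L])
      stop("level-2 partition must factorize the level-1 group grid exactly (Q_h = P'_h*Q'_h, Q_w = P'_w*Q'_w)")
  }
  structure(list(k = as.integer(k), level1 = as.integer(level1),
                 level2 = as.integer(level2), levels = as.integer(levels),
                 gate_init = gate_init),
            class = "attention_config")
}

check_partition <- function(H, W, cfg) {
  l1 <- cfg$level1
  if (H != l1[1L] * l1[3L])
    stop(sprintf("height %d is not P_h * Q_h = %d * %d", H, l1[1L], l1[3L]))
  if (W != l1[2L] * l1[4L])
    stop(sprintf("width %d is not P_w * Q_w = %d * %d", W, l1[2L], l1[4L]))
  invisible(TRUE)
}

#' Interlaced position partition
#'
#' Splits the `H x W` position grid into groups for block attention.  In
#' `"long"` mode group `(a, b)` (with `a` in `0..P_h-1`, `b` in `0..P_w-1`)
#' collects the strided, spatially distant positions
#' `(a + q_h * P_h, b + q_w * P_w)`; in `"short"` mode the groups are the
#' `Q_h * Q_w` contiguous tiles of size `P_h x P_w`.  Positions are numbered
#' column-major (`p = h + (w-1)*H`, 1-based).
#'
#' @param H,W grid size; must be divisible by the partition factors.
#' @param p_h,p_w partition factors along height and width.
#' @param mode `"long"` (strided groups) or `"short"` (contiguous tiles).
#' @return list with `groups` (list of integer position vectors), `order`
#'   (their concatenation, the forward permutation) and `inverse` (the
#'   permutation undoing it: `x[order][inverse]` is `x`).
#' @export
interlace_partition <- function(H, W, p_h, p_w, mode = c("long", "short")) {
  mode <- match.arg(mode)
  H <- as.integer(H); W <- as.integer(W)
  p_h <- as.integer(p_h); p_w <- as.integer(p_w)
  if (H %% p_h != 0L || W %% p_w != 0L)
    stop(sprintf("grid %dx%d not divisible by partition %dx%d", H, W, p_h, p_w))
  q_h <- H %/% p_h; q_w <- W %/% p_w
  groups <- vector("list", if (mode == "long") p_h * p_w else q_h * q_w)
  gi <- 0L
  if (mode == "long") {
    qh <- rep(seq_len(q_h) - 1L, times = q_w)
    qw <- rep(seq_len(q_w) - 1L, each = q_h)
    for (b in seq_len(p_w) - 1L) for (a in seq_len(p_h) - 1L) {
      gi <- gi + 1L
      groups[[gi]] <- (a + qh * p_h + 1L) + (b + qw * p_w) * H
    }
  } else {
    dh <- rep(seq_len(p_h) - 1L, times = p_w)
    dw <- rep(seq_len(p_w) - 1L, each = p_h)
    for (qb in seq_len(q_w) - 1L) for (qa in seq_len(q_h) - 1L) {
      gi <- gi + 1L
      groups[[gi]] <- (qa * p_h + dh + 1L) + (qb * p_w + dw) * H
    }
  }
  ord <- unlist(groups, use.names = FALSE)
  inv <- integer(length(ord))
  inv[ord] <- seq_along(ord)
  list(groups = groups, order = ord, inverse = inv)
}

# Group index lists for each attention application of the layer.
# levels = 2: (1) level-2 long within level-1 long parts, (2) level-2 short
# within level-1 long parts, (3) level-1 short tiles.
# levels = 1: (1) level-1 long, (2) level-1 short.
aal_group_stages <- function(H, W, cfg) {
  check_partition(H, W, cfg)
  l1 <- cfg$level1
  if (cfg$levels == 1L) {
    return(list(
      long = interlace_partition(H, W, l1[1L], l1[2L], "long")$groups,
      short = interlace_partition(H, W, l1[1L], l1[2L], "short")$groups))
  }
  l2 <- cfg$level2
  g1 <- interlace_partition(H, W, l1[1L], l1[2L], "long")$groups
  # each level-1 long group is a Q_h x Q_w grid in column-major member order
  sub_long <- interlace_partition(l1[3L], l1[4L], l2[1L], l2[2L], "long")$groups
  sub_short <- interlace_partition(l1[3L], l1[4L], l2[1L], l2[2L], "short")$groups
  st1 <- vector("list", length(g1) * length(sub_long))
  st2 <- vector("list", length(g1) * length(sub_short))
  i1 <- 0L; i2 <- 0L
  for (g in g1) {
    for (s in sub_long) { i1 <- i1 + 1L; st1[[i1]] <- g[s] }
    for (s in sub_short) { i2 <- i2 + 1L; st2[[i2]] <- g[s] }
  }
  list(long_long = st1, long_short = st2,
       short = interlace_partition(H, W, l1[1L], l1[2L], "short")$groups)
}

#' Initialize attention projection weights
#'
#' Draws the four 1x1-convolution weight matrices of one attention
#' application.  `W_f`, `W_g`, `W_h` map `C` channels down to `C/k`; `W_v`
#' maps back up.  No bias terms are used.
#'
#' @param C input channel count (must be divisible by `k`).
#' @param k channel-reduction factor.
#' @param seed optional integer seed for reproducible draws.
#' @param sd standard deviation of the Gaussian init.
#' @return list with elements `Wf`, `Wg`, `Wh` (each `C/k x C`) and
#'   `Wv` (`C x C/k`).
#' @export
attention_weights <- function(C, k = 2L, seed = NULL, sd = NULL) {
  if (C %% k != 0L) stop("C must be divisible by the channel-reduction factor k")
  cb <- C %/% k
  if (is.null(sd)) sd <- sqrt(1 / C)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  list(Wf = matrix(stats::rnorm(cb * C, sd = sd), cb, C),
       Wg = matrix(stats::rnorm(cb * C, sd = sd), cb, C),
       Wh = matrix(stats::rnorm(cb * C, sd = sd), cb, C),
       Wv = matrix(stats::rnorm(C * cb, sd = sd), C, cb))
}

check_attention_shapes <- function(X, weights) {
  if (!all(is.finite(X))) stop("non-finite values in input feature map")
  C <- nrow(X)
  if (ncol(weights$Wf) != C || ncol(weights$Wg) != C || ncol(weights$Wh) != C ||
      nrow(weights$Wv) != C)
    stop("projection weights are not dimensionally consistent with the C-channel input")
  cb <- nrow(weights$Wf)
  if (nrow(weights$Wg) != cb || nrow(weights$Wh) != cb || ncol(weights$Wv) != cb)
    stop("projection weights disagree on the reduced channel count")
  invisible(TRUE)
}

softmax_cols <- function(S) {
  mx <- S[cbind(max.col(t(S)), seq_len(ncol(S)))]
  E <- exp(S - rep(mx, each = nrow(S)))
  E / rep(colSums(E), each = nrow(S))
}

#' Scaled dot-product self-attention on one group of positions
#'
#' Computes the affinity matrix
#' `A = softmax((W_f X)^T (W_g X) / sqrt(d))`, normalized so every column
#' sums to one, and the aggregated features `Z = W_v [(W_h X) A]`.
#'
#' @param X channel-major feature matrix, `C x Q`.
#' @param weights projection weights from [attention_weights()].
#' @param d softmax temperature (scaling `d > 0`); defaults to `C/2`.
#' @return list with `A` (`Q x Q` affinity, columns sum to 1) and `Z`
#'   (`C x Q` aggregated features).
#' @export
scaled_dot_attention <- function(X, weights, d = nrow(X) / 2) {
  if (d <= 0) stop("scaling factor d must be positive")
  check_attention_shapes(X, weights)
  F <- weights$Wf %*% X
  G <- weights$Wg %*% X
  A <- softmax_cols(crossprod(F, G) / sqrt(d))
  Z <- weights$Wv %*% ((weights$Wh %*% X) %*% A)
  list(A = A, Z = Z)
}

#' Dense self-attention oracle
#'
#' Direct O(N^2) evaluation of scaled dot-product attention over all
#' positions, with an explicit per-column softmax.  Intended for
#' verification at small sizes; refuses maps larger than 4096 positions.
#'
#' @inheritParams scaled_dot_attention
#' @return list with `A` and `Z` as in [scaled_dot_attention()].
#' @export
dense_attention_oracle <- function(X, weights, d = nrow(X) / 2) {
  N <- ncol(X)
  if (N > 4096L) stop("dense oracle refused: N > 4096")
  if (d <= 0) stop("scaling factor d must be positive")
  check_attention_shapes(X, weights)
  F <- weights$Wf %*% X
  G <- weights$Wg %*% X
  H <- weights$Wh %*% X
  S <- t(F) %*% G / sqrt(d)
  A <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- exp(S[, j] - max(S[, j]))
    A[, j] <- e / sum(e)
  }
  list(A = A, Z = weights$Wv %*% (H %*% A))
}

#' Gated residual fusion
#'
#' `Y = gamma * Z + X` with a single learnable scalar gate shared over the
#' whole map.  At `gamma = 0` the attention branch is switched off and the
#' layer is the identity.
#'
#' @param Z attention output, same shape as `X`.
#' @param X input feature map.
#' @param gamma scalar gate.
#' @return matrix of the same shape as `X`.
#' @export
residual_fuse <- function(Z, X, gamma) {
  if (!identical(dim(Z), dim(X))) stop("Z and X must have the same shape")
  if (length(gamma) != 1L) stop("gamma must be a single scalar")
  gamma * Z + X
}

# Grouped attention on a position-major map (N x C): the fast path.
# Returns out (N x C, pre-gate) plus caches for backprop and MAC counts.
att_grouped_forward <- function(x, weights, groups, d) {
  F <- x %*% t(weights$Wf)
  G <- x %*% t(weights$Wg)
  Hm <- x %*% t(weights$Wh)
  cb <- ncol(F)
  isd <- 1 / sqrt(d)
  res <- .att_fwd_cpp(F, G, Hm, groups, isd)
  out <- res$z %*% t(weights$Wv)
  macs_aff <- sum(vapply(groups, function(g) 2 * length(g)^2 * cb, 0))
  list(out = out, z = res$z, F = F, G = G, H = Hm, A = res$A,
       macs_affinity = macs_aff,
       macs_projection = 4 * nrow(x) * ncol(x) * cb)
}

att_grouped_backward <- function(fwd, x, weights, groups, d, dout) {
  dz <- dout %*% weights$Wv
  dWv <- t(crossprod(fwd$z, dout))        # Wv is C x Cbar
  bk <- .att_bwd_cpp(dz, fwd$A, fwd$F, fwd$G, fwd$H, groups, 1 / sqrt(d))
  dx <- bk$dF %*% weights$Wf + bk$dG %*% weights$Wg + bk$dH %*% weights$Wh
  list(dx = dx,
       dWf = crossprod(bk$dF, x), dWg = crossprod(bk$dG, x),
       dWh = crossprod(bk$dH, x), dWv = dWv)
}

# Tape op wrapping grouped attention; wf/wg/wh are Cbar x C leaves, wv C x Cbar.
tp_attention <- function(tp, x, wf, wg, wh, wv, groups, d) {
  wts <- list(Wf = wf$v, Wg = wg$v, Wh = wh$v, Wv = wv$v)
  fwd <- att_grouped_forward(x$v, wts, groups, d)
  if (!tp$grad) { out <- fwd$out; fwd <- NULL; return(tp_node(tp, out)) }
  tp_node(tp, fwd$out, list(x, wf, wg, wh, wv), function(g, nd) {
    bk <- att_grouped_backward(fwd, nd$parents[[1]]$v, wts, groups, d, g)
    list(bk$dx, bk$dWf, bk$dWg, bk$dWh, bk$dWv)
  })
}

att_grouped <- function(X, weights, groups, d) {
  # channel-major wrapper around the position-major kernel
  t(att_grouped_forward(t(X), weights, groups, d)$out)
}

#' Long-range block attention
#'
#' Applies scaled dot-product attention independently within each strided
#' long-range group of the level-1 partition and merges the results back
#' into place.  The implied global affinity is block-diagonal after the
#' interlacing permutation.
#'
#' @param X channel-major feature map `C x N` with `N = H * W`.
#' @param weights projection weights ([attention_weights()]).
#' @param cfg an [attention_config()].
#' @param H,W spatial grid size.
#' @param d softmax temperature; defaults to `C/2`.
#' @return the merged `C x N` attention output (no residual gate applied).
#' @export
long_range_attention <- function(X, weights, cfg, H, W, d = nrow(X) / 2) {
  check_partition(H, W, cfg)
  check_attention_shapes(X, weights)
  g <- interlace_partition(H, W, cfg$level1[1L], cfg$level1[2L], "long")$groups
  att_grouped(X, weights, g, d)
}

#' Short-range block attention
#'
#' As [long_range_attention()], with attention restricted to the contiguous
#' `P_h x P_w` tiles of the level-1 partition.
#'
#' @inheritParams long_range_attention
#' @return the merged `C x N` attention output (no residual gate applied).
#' @export
short_range_attention <- function(X, weights, cfg, H, W, d = nrow(X) / 2) {
  check_partition(H, W, cfg)
  check_attention_shapes(X, weights)
  g <- interlace_partition(H, W, cfg$level1[1L], cfg$level1[2L], "short")$groups
  att_grouped(X, weights, g, d)
}

#' Initialize the full attention-aware layer
#'
#' One independent projection-weight set and residual gate per attention
#' application: three for the two-level decomposition (level-2 long,
#' level-2 short, level-1 short), two for the single-level interlaced
#' configuration.
#'
#' @param C channel count of the maps the layer is applied to.
#' @param cfg an [attention_config()].
#' @param seed optional integer seed.
#' @return list of per-stage lists, each with `weights` and `gamma`.
#' @export
aal_init <- function(C, cfg, seed = NULL) {
  nstage <- if (cfg$levels == 2L) 3L else 2L
  lapply(seq_len(nstage), function(s) {
    list(weights = attention_weights(C, cfg$k,
                                     seed = if (is.null(seed)) NULL else seed + s),
         gamma = cfg$gate_init)
  })
}

#' Attention-aware layer forward pass
#'
#' The composed sparse-attention operator.  With `levels = 2`: within each
#' level-1 long-range part, level-2 long-range attention then level-2
#' short-range attention are applied; the merged result is passed through
#' level-1 short-range attention.  Each application uses its own projection
#' weights and is residual-gated (`Y = gamma * Z + X`).  With `levels = 1`
#' the layer is level-1 long followed by level-1 short.
#'
#' @param X channel-major feature map `C x N`.
#' @param stages per-stage parameters from [aal_init()].
#' @param cfg an [attention_config()].
#' @param H,W spatial grid size.
#' @param d softmax temperature; defaults to `C/2`.
#' @return the `C x N` output feature map.
#' @export
attention_aware_layer <- function(X, stages, cfg, H, W, d = nrow(X) / 2) {
  gs <- aal_group_stages(H, W, cfg)
  if (length(gs) != length(stages))
    stop(sprintf("layer has %d attention stages but %d parameter sets supplied",
                 length(gs), length(stages)))
  x <- t(X)
  for (s in seq_along(gs)) {
    z <- att_grouped_forward(x, stages[[s]]$weights, gs[[s]], d)$out
    x <- stages[[s]]$gamma * z + x
  }
  t(x)
}

#' Assembled effective affinity of a grouped attention pass
#'
#' Places each group's `Q x Q` affinity block into the full `N x N` matrix;
#' all cross-group entries are exactly zero (the block-diagonal structure of
#' the factorized scheme, up to the interlacing permutation).
#'
#' @param X channel-major feature map `C x N`.
#' @param weights projection weights.
#' @param groups list of position-index groups (e.g. from
#'   [interlace_partition()]).
#' @param d softmax temperature; defaults to `C/2`.
#' @return `N x N` matrix; entry `(i, j)` is the weight with which output
#'   position `j` draws on key position `i`.
#' @export
effective_affinity <- function(X, weights, groups, d = nrow(X) / 2) {
  N <- ncol(X)
  A <- matrix(0, N, N)
  for (idx in groups) {
    blk <- scaled_dot_attention(X[, idx, drop = FALSE], weights, d)$A
    A[idx, idx] <- blk
  }
  A
}

#' Boolean support pattern of a grouped attention pass
#'
#' @param groups list of position-index groups.
#' @param N total number of positions.
#' @return `N x N` logical-valued 0/1 matrix marking which (key, query)
#'   pairs can interact.
#' @export
support_pattern <- function(groups, N) {
  S <- matrix(0, N, N)
  for (idx in groups) S[idx, idx] <- 1
  S
}

## ---- operation counts ----

#' Operation counts of the attention schemes
#'
#' Evaluates the printed complexity formulas of the three schemes: dense
#' self-attention, `4HWC^2/k + 2(HW)^2 C/k`; interlaced (one-level)
#' factorization, `4HWC^2/k + (3/2)(HW)^2 (C/k) (1/(P_h P_w) + 1/(Q_h Q_w))`;
#' and the two-level decomposition,
#' `12HWC^2/k + 2(HW)^2 (C/k) ((1/(P_h P_w))(1/(P'_h P'_w) + 1/(Q'_h Q'_w)) + 1/(Q_h Q_w))`.
#' Counting convention: one multiply-accumulate is one operation; softmax,
#' the `1/sqrt(d)` scaling and additions are not counted.
#'
#' @param H,W,C spatial size and channel count of the feature map.
#' @param k channel-reduction factor.
#' @param scheme `"dense"`, `"interlaced"` or `"two_level"`.
#' @param cfg an [attention_config()] (required for the factorized schemes).
#' @return object of class `"op_count"`: list with `projection_ops`,
#'   `affinity_ops` and `total`.
#' @export
op_count_complexity <- function(H, W, C, k, scheme = c("dense", "interlaced", "two_level"),
                                cfg = NULL) {
  scheme <- match.arg(scheme)
  N <- H * W
  if (C %% k != 0) stop("C must be divisible by k")
  if (scheme == "dense") {
    proj <- 4 * N * C^2 / k
    aff <- 2 * N^2 * C / k
  } else {
    if (is.null(cfg)) stop("cfg required for factorized schemes")
    check_partition(H, W, cfg)
    p1 <- cfg$level1[1L] * cfg$level1[2L]
    q1 <- cfg$level1[3L] * cfg$level1[4L]
    if (scheme == "interlaced") {
      proj <- 4 * N * C^2 / k
      aff <- 1.5 * N^2 * (C / k) * (1 / p1 + 1 / q1)
    } else {
      if (cfg$levels != 2L) stop("two_level scheme needs a levels = 2 config")
      p2 <- cfg$level2[1L] * cfg$level2[2L]
      q2 <- cfg$level2[3L] * cfg$level2[4L]
      proj <- 12 * N * C^2 / k
      aff <- 2 * N^2 * (C / k) * ((1 / p1) * (1 / p2 + 1 / q2) + 1 / q1)
    }
  }
  structure(list(projection_ops = proj, affinity_ops = aff, total = proj + aff),
            class = "op_count")
}

#' @export
print.op_count <- function(x, ...) {
  cat(sprintf("attention op count: projection %.0f + affinity %.0f = %.0f MACs\n",
              x$projection_ops, x$affinity_ops, x$total))
  invisible(x)
}

#' Minimized affinity-term cost at the optimal partition
#'
#' The affinity term of the factorized schemes, evaluated at the
#' (real-valued) cost-minimizing partition product: `P_h P_w = (HW)^{1/2}`
#' for the interlaced scheme and `P_h P_w = (HW)^{1/3}` (with the second
#' level split at the square root of the remaining group size) for the
#' two-level scheme.  Used for scaling analysis; the products need not be
#' realizable integers.
#'
#' @inheritParams op_count_complexity
#' @return the affinity-term operation count (a real number).
#' @export
op_count_minimized_affinity <- function(H, W, C, k,
                                        scheme = c("interlaced", "two_level")) {
  scheme <- match.arg(scheme)
  N <- H * W
  if (scheme == "interlaced") {
    p1 <- sqrt(N)
    1.5 * N^2 * (C / k) * (1 / p1 + p1 / N)
  } else {
    p1 <- N^(1 / 3)
    q1 <- N / p1
    p2 <- sqrt(q1)
    2 * N^2 * (C / k) * ((1 / p1) * (1 / p2 + p2 / q1) + 1 / q1)
  }
}

#' Empirical multiply-accumulate count of the implemented layer
#'
#' Instruments the grouped-attention implementation on a random map and
#' returns the actually executed affinity-product MACs (the two `Q x Q`
#' matrix products per group, `2 Q^2 C/k` each) and projection MACs.
#'
#' @inheritParams op_count_complexity
#' @param seed seed for the probe map.
#' @return object of class `"op_count"`.
#' @export
op_count_measured <- function(H, W, C, k, scheme = c("dense", "interlaced", "two_level"),
                              cfg = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(seed)
  N <- H * W
  x <- matrix(stats::rnorm(N * C), N, C)
  wts <- attention_weights(C, k, seed = seed)
  groups_per_pass <- switch(scheme,
    dense = list(list(seq_len(N))),
    interlaced = {
      cfg1 <- cfg
      stopifnot(!is.null(cfg1))
      aal_group_stages(H, W, attention_config(k = cfg1$k, level1 = cfg1$level1,
                                              levels = 1L))
    },
    two_level = {
      stopifnot(!is.null(cfg), cfg$levels == 2L)
      aal_group_stages(H, W, cfg)
    })
  aff <- 0; proj <- 0
  for (g in groups_per_pass) {
    fwd <- att_grouped_forward(x, wts, g, C / 2)
    aff <- aff + fwd$macs_affinity
    proj <- proj + fwd$macs_projection
  }
  structure(list(projection_ops = proj, affinity_ops = aff, total = proj + aff),
            class = "op_count")
}
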