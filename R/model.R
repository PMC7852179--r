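# The interpolation network: siamese residual dense feature extractor,
# attention-driven warp synthesis heads, and the sigmoid-mask fusion net.
#
# All parameters live in one flat named list; the forward pass builds a tape
# and returns the prediction node, so one backward call yields every
# gradient.  Batch-norm running statistics live in a mutable `state`
# environment owned by the model object.

#' Backbone (residual dense network) configuration
#'
#' Shallow feature extraction (two 3x3 convs), `D` residual dense blocks
#' (each `convs_per_block` ReLU convs with `growth` new channels
#' concatenated, then a 1x1 local fusion and a local residual), global
#' feature fusion (1x1 + 3x3 convs and a global residual), and a final 3x3
#' conv to `C` output channels.  No pooling anywhere: the spatial size is
#' preserved end to end.
#'
#' @param G0 base channel count of the trunk.
#' @param D number of residual dense blocks.
#' @param convs_per_block convolutions per block.
#' @param growth channels added by each in-block convolution.
#' @param C output feature channels (input to the attention layer).
#' @return object of class `"srdn_config"`.
#' @export
srdn_config <- function(G0 = 32L, D = 4L, convs_per_block = 4L,
                        growth = 16L, C = 64L) {
  stopifnot(G0 >= 1, D >= 1, convs_per_block >= 1, growth >= 1, C >= 1)
  structure(list(G0 = as.integer(G0), D = as.integer(D),
                 convs_per_block = as.integer(convs_per_block),
                 growth = as.integer(growth), C = as.integer(C)),
            class = "srdn_config")
}

#' Full model configuration
#'
#' @param srdn a [srdn_config()].
#' @param attention an [attention_config()]; its `k` must divide the
#'   backbone's output channels `C`.
#' @param fusion_width channel width of the fusion network's hidden layer.
#' @param preset `"default"` (the full-size network) or `"tiny"` (a small
#'   CPU-scale variant: `D = 2`, 2 convs per block, growth 8, `C = 16`);
#'   explicit `srdn`/`attention` arguments override the preset.
#' @return object of class `"ssan_config"`.
#' @export
ssan_config <- function(srdn = NULL, attention = NULL, fusion_width = NULL,
                        preset = c("default", "tiny")) {
  preset <- match.arg(preset)
  if (is.null(srdn))
    srdn <- if (preset == "tiny")
      srdn_config(G0 = 8L, D = 2L, convs_per_block = 2L, growth = 8L, C = 16L)
    else srdn_config()
  if (is.null(attention))
    attention <- if (preset == "tiny")
      attention_config(k = 2L, level1 = c(4L, 4L, 16L, 16L), level2 = c(4L, 4L, 4L, 4L))
    else attention_config(k = 2L, level1 = c(8L, 8L, 64L, 64L), level2 = c(8L, 8L, 8L, 8L))
  if (is.null(fusion_width)) fusion_width <- if (preset == "tiny") 8L else 32L
  if (srdn$C %% attention$k != 0L)
    stop("backbone output channels C must be divisible by the attention reduction k")
  structure(list(srdn = srdn, attention = attention,
                 fusion_width = as.integer(fusion_width), preset = preset),
            class = "ssan_config")
}

he_init <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / fan)), nin, nout)

#' Initialize model parameters
#'
#' @param cfg an [ssan_config()].
#' @param seed integer seed for the weight draws.
#' @return object of class `"ssan_model"`: flat parameter list, config, and
#'   a state environment holding batch-norm running statistics.
#' @export
ssan_init <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ssan_config"))
  s <- cfg$srdn
  p <- list()
  with_seed(seed, {
    p[["sfe1.w"]] <- he_init(9L * 2L, s$G0, 9 * 2)
    p[["sfe1.b"]] <- matrix(0, 1L, s$G0)
    p[["sfe2.w"]] <- he_init(9L * s$G0, s$G0, 9 * s$G0)
    p[["sfe2.b"]] <- matrix(0, 1L, s$G0)
    for (d in seq_len(s$D)) {
      cin <- s$G0
      for (c in seq_len(s$convs_per_block)) {
        p[[sprintf("rdb%d.c%d.w", d, c)]] <- he_init(9L * cin, s$growth, 9 * cin)
        p[[sprintf("rdb%d.c%d.b", d, c)]] <- matrix(0, 1L, s$growth)
        cin <- cin + s$growth
      }
      p[[sprintf("rdb%d.lf.w", d)]] <- he_init(cin, s$G0, cin)
      p[[sprintf("rdb%d.lf.b", d)]] <- matrix(0, 1L, s$G0)
    }
    p[["dff1.w"]] <- he_init(s$D * s$G0, s$G0, s$D * s$G0)
    p[["dff1.b"]] <- matrix(0, 1L, s$G0)
    p[["dff2.w"]] <- he_init(9L * s$G0, s$G0, 9 * s$G0)
    p[["dff2.b"]] <- matrix(0, 1L, s$G0)
    p[["fea.w"]] <- he_init(9L * s$G0, s$C, 9 * s$G0)
    p[["fea.b"]] <- matrix(0, 1L, s$C)
    nstage <- if (cfg$attention$levels == 2L) 3L else 2L
    cb <- s$C %/% cfg$attention$k
    for (st in seq_len(nstage)) {
      p[[sprintf("aal%d.wf", st)]] <- he_init(cb, s$C, s$C)
      p[[sprintf("aal%d.wg", st)]] <- he_init(cb, s$C, s$C)
      p[[sprintf("aal%d.wh", st)]] <- he_init(cb, s$C, s$C)
      p[[sprintf("aal%d.wv", st)]] <- he_init(s$C, cb, cb)
      p[[sprintf("aal%d.gamma", st)]] <- matrix(cfg$attention$gate_init, 1L, 1L)
    }
    # residual warp head: zero-init so each warp starts as its source frame
    p[["head.w"]] <- matrix(0, s$C, 1L)
    p[["head.b"]] <- matrix(0, 1L, 1L)
    fin <- 2L * s$C + 2L
    p[["fus1.w"]] <- he_init(9L * fin, cfg$fusion_width, 9 * fin)
    p[["fus1.b"]] <- matrix(0, 1L, cfg$fusion_width)
    p[["bn.gamma"]] <- matrix(1, 1L, cfg$fusion_width)
    p[["bn.beta"]] <- matrix(0, 1L, cfg$fusion_width)
    p[["fus2.w"]] <- he_init(9L * cfg$fusion_width, 1L, 9 * cfg$fusion_width)
    p[["fus2.b"]] <- matrix(0, 1L, 1L)
  })
  state <- new.env(parent = emptyenv())
  state$bn_mean <- rep(0, cfg$fusion_width)
  state$bn_var <- rep(1, cfg$fusion_width)
  structure(list(params = p, cfg = cfg, state = state, seed = as.integer(seed),
                 schema_version = 1L),
            class = "ssan_model")
}

# Create one leaf node per parameter on a fresh tape.
make_leaves <- function(tp, params) lapply(params, function(v) tp_leaf(tp, v))

# Residual dense network trunk on B stacked 2-channel inputs ((B*N) x 2).
srdn_forward_tp <- function(tp, lv, x, H, W, s, B = 1L) {
  f_1 <- tp_conv3(tp, x, lv[["sfe1.w"]], lv[["sfe1.b"]], H, W, B)
  cur <- tp_conv3(tp, f_1, lv[["sfe2.w"]], lv[["sfe2.b"]], H, W, B)
  blocks <- vector("list", s$D)
  for (d in seq_len(s$D)) {
    feats <- list(cur)
    for (c in seq_len(s$convs_per_block)) {
      cat_in <- if (length(feats) == 1L) feats[[1L]] else tp_cbind(tp, feats)
      g <- tp_relu(tp, tp_conv3(tp, cat_in, lv[[sprintf("rdb%d.c%d.w", d, c)]],
                                lv[[sprintf("rdb%d.c%d.b", d, c)]], H, W, B))
      feats <- c(feats, list(g))
    }
    lf <- tp_conv1(tp, tp_cbind(tp, feats), lv[[sprintf("rdb%d.lf.w", d)]],
                   lv[[sprintf("rdb%d.lf.b", d)]])
    cur <- tp_add(tp, lf, cur)          # local residual
    blocks[[d]] <- cur
  }
  gf <- tp_conv1(tp, tp_cbind(tp, blocks), lv[["dff1.w"]], lv[["dff1.b"]])
  gf <- tp_conv3(tp, gf, lv[["dff2.w"]], lv[["dff2.b"]], H, W, B)
  gf <- tp_add(tp, gf, f_1)             # global residual
  tp_conv3(tp, gf, lv[["fea.w"]], lv[["fea.b"]], H, W, B)
}

# Replicate per-sample position groups across B stacked samples.
offset_groups <- function(groups, N, B) {
  if (B == 1L) return(groups)
  unlist(lapply(seq_len(B) - 1L, function(b)
    lapply(groups, function(g) g + b * N)), recursive = FALSE)
}

# Attention-aware layer + 1x1 head on B stacked feature maps.
warp_head_tp <- function(tp, lv, feat, groups_stages, d) {
  cur <- feat
  for (st in seq_along(groups_stages)) {
    z <- tp_attention(tp, cur, lv[[sprintf("aal%d.wf", st)]],
                      lv[[sprintf("aal%d.wg", st)]], lv[[sprintf("aal%d.wh", st)]],
                      lv[[sprintf("aal%d.wv", st)]], groups_stages[[st]], d)
    gz <- tp_mul(tp, lv[[sprintf("aal%d.gamma", st)]], z)
    cur <- tp_add(tp, gz, cur)
  }
  tp_conv1(tp, cur, lv[["head.w"]], lv[["head.b"]])
}

# Full forward pass for a batch of frame pairs on one tape.  `pairs` is a
# list of list(f0, f2) H x W matrices; all samples (and both siamese
# directions) are stacked row-wise so every layer is a single tape node.
# Returns stacked prediction node (pre-clamp) plus diagnostics.
ssan_forward_batch <- function(tp, lv, model, pairs, train = TRUE) {
  cfg <- model$cfg
  s <- cfg$srdn
  H <- nrow(pairs[[1L]]$f0); W <- ncol(pairs[[1L]]$f0)
  N <- H * W
  B <- length(pairs)
  groups <- aal_group_stages(H, W, cfg$attention)
  groups2b <- lapply(groups, offset_groups, N = N, B = 2L * B)
  d <- s$C / 2
  f0s <- do.call(rbind, lapply(pairs, function(p) matrix(as.vector(p$f0), ncol = 1L)))
  f2s <- do.call(rbind, lapply(pairs, function(p) matrix(as.vector(p$f2), ncol = 1L)))
  x_all <- tp_const(tp, rbind(cbind(f0s, f2s), cbind(f2s, f0s)))
  feat <- srdn_forward_tp(tp, lv, x_all, H, W, s, 2L * B)
  # each direction's warp is predicted as a residual on its source frame
  warp <- tp_add(tp, tp_const(tp, rbind(f0s, f2s)),
                 warp_head_tp(tp, lv, feat, groups2b, d))
  fwd_rows <- seq_len(B * N)
  rev_rows <- B * N + fwd_rows
  w0 <- tp_rows(tp, warp, fwd_rows)
  w1 <- tp_rows(tp, warp, rev_rows)
  Ff <- tp_rows(tp, feat, fwd_rows)
  Fr <- tp_rows(tp, feat, rev_rows)
  fin <- tp_cbind(tp, list(Ff, Fr, w0, w1))
  c1 <- tp_conv3(tp, fin, lv[["fus1.w"]], lv[["fus1.b"]], H, W, B)
  if (train) {
    bn <- tp_bn(tp, c1, lv[["bn.gamma"]], lv[["bn.beta"]])
    mom <- 0.1
    model$state$bn_mean <- (1 - mom) * model$state$bn_mean + mom * attr(bn, "batch_mean")
    model$state$bn_var <- (1 - mom) * model$state$bn_var + mom * attr(bn, "batch_var")
  } else {
    bn <- tp_bn_eval(tp, c1, lv[["bn.gamma"]], lv[["bn.beta"]],
                     model$state$bn_mean, model$state$bn_var)
  }
  act <- tp_relu(tp, bn)
  m_logit <- tp_conv3(tp, act, lv[["fus2.w"]], lv[["fus2.b"]], H, W, B)
  M <- tp_sigmoid(tp, m_logit)
  pred <- tp_add(tp, w1, tp_mul(tp, M, tp_sub(tp, w0, w1)))
  list(pred = pred, M = M$v, w0 = w0$v, w1 = w1$v, B = B, N = N, H = H, W = W)
}

# Batched inference: list of pairs -> list of clamped H x W images.
ssan_predict_pairs <- function(model, pairs, chunk = 8L) {
  H <- nrow(pairs[[1L]]$f0); W <- ncol(pairs[[1L]]$f0)
  check_partition(H, W, model$cfg$attention)
  out <- vector("list", length(pairs))
  at <- 1L
  while (at <= length(pairs)) {
    ids <- at:min(at + chunk - 1L, length(pairs))
    tp <- tape_new(grad = FALSE)
    lv <- make_leaves(tp, model$params)
    res <- ssan_forward_batch(tp, lv, model, pairs[ids], train = FALSE)
    for (k in seq_along(ids)) {
      rows <- (k - 1L) * res$N + seq_len(res$N)
      out[[ids[k]]] <- matrix(clamp01(res$pred$v[rows, 1L]), H, W)
    }
    at <- at + chunk
  }
  out
}

# Convenience: single-pair inference returning the clamped H x W image.
ssan_predict_pair <- function(model, f0, f2) {
  check_same_shape(f0, f2, "input frames")
  ssan_predict_pairs(model, list(list(f0 = f0, f2 = f2)))[[1L]]
}

## ---- public backbone surface ----

#' Extract bidirectional siamese features
#'
#' Applies the weight-shared residual dense extractor to the channel-stacked
#' ordered pair `(prev, next)` and to `(next, prev)`; direction is encoded
#' purely by channel order, so swapping the inputs swaps the two outputs
#' exactly.
#'
#' @param model an `"ssan_model"` (from [ssan_init()]) or a fitted
#'   [ssan_fit()] object.
#' @param prev,next_ grayscale frames (`H x W` matrices in `[0, 1]`).
#' @return list with `F_fwd` and `F_rev`, each a `C x N` channel-major
#'   feature matrix with attributes `H`, `W`.
#' @export
extract_features <- function(model, prev, next_) {
  model <- as_ssan_model(model)
  check_same_shape(prev, next_, "input frames")
  check_image(prev); check_image(next_)
  H <- nrow(prev); W <- ncol(prev)
  tp <- tape_new(grad = FALSE)
  lv <- make_leaves(tp, model$params)
  p0 <- matrix(as.vector(prev), ncol = 1L)
  p2 <- matrix(as.vector(next_), ncol = 1L)
  Ff <- srdn_forward_tp(tp, lv, tp_const(tp, cbind(p0, p2)), H, W, model$cfg$srdn)
  Fr <- srdn_forward_tp(tp, lv, tp_const(tp, cbind(p2, p0)), H, W, model$cfg$srdn)
  mk <- function(nd) structure(t(nd$v), H = H, W = W)
  list(F_fwd = mk(Ff), F_rev = mk(Fr))
}

#' Synthesize a warped frame from one direction's features
#'
#' Runs the attention-aware layer over the feature map, projects to a
#' single channel with the linear 1x1 head, and adds the direction's source
#' frame: the head predicts a residual correction, so the warp equals the
#' source frame at initialization.  The output is linear (unclamped);
#' `warp_0` comes from the forward features and frame `t-1`, `warp_1` from
#' the reverse features and frame `t+1`.
#'
#' @param model an `"ssan_model"` or fitted [ssan_fit()] object.
#' @param feature a `C x N` feature matrix with `H`/`W` attributes, as
#'   returned by [extract_features()].
#' @param frame the direction's source frame (`H x W` matrix).
#' @return `H x W` matrix.
#' @export
synthesize_warp <- function(model, feature, frame) {
  model <- as_ssan_model(model)
  H <- attr(feature, "H"); W <- attr(feature, "W")
  if (is.null(H)) stop("feature must carry H/W attributes (see extract_features)")
  if (nrow(feature) != model$cfg$srdn$C)
    stop("feature channel count does not match the model configuration")
  check_same_shape(frame, matrix(0, H, W), "frame and feature grid")
  tp <- tape_new(grad = FALSE)
  lv <- make_leaves(tp, model$params)
  groups <- aal_group_stages(H, W, model$cfg$attention)
  w <- warp_head_tp(tp, lv, tp_const(tp, t(feature)), groups, model$cfg$srdn$C / 2)
  frame + matrix(w$v, H, W)
}

#' Fuse two warped frames into the interpolated image
#'
#' The hybrid fusion network maps the concatenated features and warps to a
#' sigmoid weight mask `M` (entries strictly inside `(0, 1)`) and blends
#' `M * warp_0 + (1 - M) * warp_1`, clamping the result to `[0, 1]`.
#'
#' @param model an `"ssan_model"` or fitted [ssan_fit()] object.
#' @param warp_0,warp_1 `H x W` warped-frame estimates.
#' @param features list with `F_fwd`, `F_rev` from [extract_features()].
#' @return list with `image` (clamped), `raw` (pre-clamp blend) and
#'   `mask`.
#' @export
fuse_warps <- function(model, warp_0, warp_1, features) {
  model <- as_ssan_model(model)
  check_same_shape(warp_0, warp_1, "warped frames")
  H <- nrow(warp_0); W <- ncol(warp_0)
  tp <- tape_new(grad = FALSE)
  lv <- make_leaves(tp, model$params)
  fin <- tp_const(tp, cbind(t(features$F_fwd), t(features$F_rev),
                            as.vector(warp_0), as.vector(warp_1)))
  c1 <- tp_conv3(tp, fin, lv[["fus1.w"]], lv[["fus1.b"]], H, W)
  bn <- tp_bn_eval(tp, c1, lv[["bn.gamma"]], lv[["bn.beta"]],
                   model$state$bn_mean, model$state$bn_var)
  act <- tp_relu(tp, bn)
  M <- 1 / (1 + exp(-(tp_conv3(tp, act, lv[["fus2.w"]], lv[["fus2.b"]], H, W)$v)))
  raw <- M * as.vector(warp_0) + (1 - M) * as.vector(warp_1)
  list(image = matrix(clamp01(raw), H, W), raw = matrix(raw, H, W),
       mask = matrix(M, H, W))
}

as_ssan_model <- function(x) {
  if (inherits(x, "ssan")) x$model
  else if (inherits(x, "ssan_model")) x
  else stop("expected an 'ssan_model' or fitted 'ssan' object")
}
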