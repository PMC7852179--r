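# Training objectives: Gram-matrix style losses, the adaptive style-balance
# loss with sign-switching supervision from the two input frames, feature
# reconstruction, the Charbonnier pixel term, and their weighted total.

#' Loss weights and constants
#'
#' @param alpha1,alpha2,alpha3 trade-off weights of the total loss
#'   (style-balance, feature-reconstruction and pixel terms); defaults
#'   `1e6, 1, 1`.
#' @param beta style-balance weights for the supervision against frames
#'   0, 1 (ground truth) and 2; defaults `0.1, 1, 0.1`.
#' @param eps Charbonnier constant, default `1e-6`.
#' @return object of class `"loss_weights"`.
#' @export
loss_weights <- function(alpha1 = 1e6, alpha2 = 1, alpha3 = 1,
                         beta = c(0.1, 1, 0.1), eps = 1e-6) {
  stopifnot(alpha1 >= 0, alpha2 >= 0, alpha3 >= 0, all(beta >= 0),
            length(beta) == 3L, eps >= 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 beta = beta, eps = eps),
            class = "loss_weights")
}

#' Gram matrix of a feature map
#'
#' `G[c, c'] = (1 / (C * H * W)) * sum_{h, w} F[c, h, w] * F[c', h, w]`:
#' the channel co-activation summary used as a style statistic.
#'
#' @param feature a `C x H x W` array, or an `H x W` matrix (taken as a
#'   single channel).
#' @return symmetric `C x C` matrix.
#' @export
gram_matrix <- function(feature) {
  if (is.matrix(feature)) feature <- array(feature, c(1L, dim(feature)))
  if (length(dim(feature)) != 3L) stop("feature must be C x H x W")
  if (length(feature) == 0L) stop("empty feature map")
  if (!all(is.finite(feature))) stop("non-finite values in feature map")
  C <- dim(feature)[1L]
  Fm <- matrix(aperm(feature, c(2L, 3L, 1L)), ncol = C)   # (H*W) x C
  crossprod(Fm) / length(feature)
}

# Gram matrices of all phi layers for an image (values only).
phi_grams <- function(phi, img) {
  lapply(phi_apply(phi, img), function(l) crossprod(l$values) / length(l$values))
}

#' Style reconstruction loss
#'
#' Sum over the feature layers of the squared Frobenius distance between
#' the Gram matrices of the two images.
#'
#' @param x,y images (`H x W` matrices in `[0, 1]`).
#' @param phi a [feature_network()].
#' @return nonnegative scalar.
#' @export
style_reconstruction_loss <- function(x, y, phi) {
  check_same_shape(x, y)
  gx <- phi_grams(phi, x)
  gy <- phi_grams(phi, y)
  sum(vapply(seq_along(gx), function(j) sum((gx[[j]] - gy[[j]])^2), 0))
}

#' Adaptive style-balance loss
#'
#' `sum_{j=0..2} beta_j * sign(L_style(pred, frame_j) - L_style(gt, frame_j))
#'  * L_style(pred, frame_j)`, where frame 1 is the ground truth itself.
#' The sign gate compares the prediction's style distance to frame `j`
#' against the ground truth's: while the prediction is stylistically farther
#' from a neighbour frame than the ground truth is, the term is positive and
#' pulls the prediction's style toward that frame; once it is closer, the
#' sign flips and pushes it away, balancing the transition.  `sign(0)` is
#' taken as 0, so the loss vanishes exactly at `pred == gt`.
#'
#' @param frame0,gt,pred,frame2 images of identical shape: the two input
#'   frames, the ground-truth middle frame and the synthesized frame.
#' @param phi a [feature_network()].
#' @param weights a [loss_weights()] (only `beta` is used).
#' @return list with `value` and the three signed `terms`.
#' @export
style_balance_loss <- function(frame0, gt, pred, frame2, phi,
                               weights = loss_weights()) {
  check_same_shape(frame0, gt); check_same_shape(gt, pred)
  check_same_shape(pred, frame2)
  frames <- list(frame0, gt, frame2)
  terms <- vapply(1:3, function(i) {
    lp <- style_reconstruction_loss(pred, frames[[i]], phi)
    lg <- style_reconstruction_loss(gt, frames[[i]], phi)
    weights$beta[i] * sign(lp - lg) * lp
  }, 0)
  list(value = sum(terms), terms = terms)
}

#' Feature reconstruction loss
#'
#' Sum over the feature layers of the mean squared activation difference,
#' `(1 / (C_j H_j W_j)) * ||phi_j(pred) - phi_j(gt)||_2^2`.
#'
#' @param pred,gt images of identical shape.
#' @param phi a [feature_network()].
#' @return nonnegative scalar.
#' @export
feature_reconstruction_loss <- function(pred, gt, phi) {
  check_same_shape(pred, gt)
  fp <- phi_apply(phi, pred)
  fg <- phi_apply(phi, gt)
  sum(vapply(seq_along(fp), function(j) {
    sum((fp[[j]]$values - fg[[j]]$values)^2) / length(fp[[j]]$values)
  }, 0))
}

#' Charbonnier pixel loss
#'
#' `sum_x sqrt((pred(x) - gt(x))^2 + eps^2)`: a smooth robust penalty with
#' floor `N * eps` attained exactly at `pred == gt`.
#'
#' @param pred,gt images of identical shape.
#' @param eps smoothing constant, default `1e-6`.
#' @return nonnegative scalar.
#' @export
charbonnier_loss <- function(pred, gt, eps = 1e-6) {
  check_same_shape(pred, gt)
  d <- pred - gt
  sum(sqrt(d * d + eps * eps))
}

#' Total training loss
#'
#' `alpha1 * L_bs + alpha2 * L_f + alpha3 * L_1` with the per-term
#' breakdown returned for logging.
#'
#' @inheritParams style_balance_loss
#' @param weights a [loss_weights()].
#' @return list with `total`, `bs`, `f`, `l1` (weighted contributions are
#'   `alpha * term`), and `bs_terms` (the three signed style-balance terms).
#' @export
total_loss <- function(frame0, gt, pred, frame2, phi, weights = loss_weights()) {
  bs <- style_balance_loss(frame0, gt, pred, frame2, phi, weights)
  lf <- feature_reconstruction_loss(pred, gt, phi)
  l1 <- charbonnier_loss(pred, gt, weights$eps)
  list(total = weights$alpha1 * bs$value + weights$alpha2 * lf + weights$alpha3 * l1,
       bs = bs$value, f = lf, l1 = l1, bs_terms = bs$terms)
}

## ---- tape version used during training ----

# Batched total loss.  `pred` is a (B*N) x 1 node of B stacked H x W
# predictions; `triplets` is a list of B lists of three plain frames.  The
# sign gates are evaluated from the current values and treated as constants
# (no gradient through the sign), so gradients flow only through the style
# distances of the prediction.  Returns the summed total-loss node plus a
# B x 6 per-sample term matrix (bs, f, l1, signed bs terms) for logging.
tp_total_loss_batch <- function(tp, pred, triplets, phi, weights, H, W) {
  B <- length(triplets)
  N <- H * W
  gt_stack <- do.call(rbind, lapply(triplets, function(fr)
    matrix(as.vector(fr[[2L]]), ncol = 1L)))

  layers_pred <- phi_apply_tape(phi, tp, pred, H, W, B)
  # frozen features of the ground truth, off the gradient tape
  tpc <- tape_new(grad = FALSE)
  layers_gt <- phi_apply_tape(phi, tpc, tp_const(tpc, gt_stack), H, W, B)

  # per-sample Gram matrices of the prediction, on tape
  grams_pred <- lapply(seq_len(B), function(i)
    lapply(layers_pred, function(l) {
      nj <- l$H * l$W
      tp_gram(tp, tp_rows(tp, l$node, (i - 1L) * nj + seq_len(nj)))
    }))
  per_sample <- matrix(0, B, 6L,
                       dimnames = list(NULL, c("bs", "f", "l1", "bs0", "bs1", "bs2")))
  total <- NULL
  for (i in seq_len(B)) {
    fr <- triplets[[i]]
    grams_f <- lapply(fr, function(img) phi_grams(phi, img))   # frames 0, 1, 2
    style_to <- function(gconst) {
      acc <- NULL
      for (j in seq_along(grams_pred[[i]])) {
        t_j <- tp_frob2(tp, grams_pred[[i]][[j]], gconst[[j]])
        acc <- if (is.null(acc)) t_j else tp_add(tp, acc, t_j)
      }
      acc
    }
    ls_pred <- lapply(grams_f, style_to)
    ls_gt <- vapply(1:3, function(k) {
      sum(vapply(seq_along(grams_f[[2L]]), function(j)
        sum((grams_f[[2L]][[j]] - grams_f[[k]][[j]])^2), 0))
    }, 0)
    signs <- vapply(1:3, function(k) sign(ls_pred[[k]]$v - ls_gt[k]), 0)
    bs_terms <- weights$beta * signs * vapply(ls_pred, function(n) n$v, 0)
    bs <- tp_scale(tp, ls_pred[[1L]], weights$beta[1L] * signs[1L])
    bs <- tp_add(tp, bs, tp_scale(tp, ls_pred[[2L]], weights$beta[2L] * signs[2L]))
    bs <- tp_add(tp, bs, tp_scale(tp, ls_pred[[3L]], weights$beta[3L] * signs[3L]))
    per_sample[i, c(1L, 4L, 5L, 6L)] <- c(bs$v, bs_terms)
    total <- if (is.null(total)) tp_scale(tp, bs, weights$alpha1)
             else tp_add(tp, total, tp_scale(tp, bs, weights$alpha1))
  }

  # feature reconstruction: stacked layers sum over samples at one scale
  lf <- NULL
  for (j in seq_along(layers_pred)) {
    sc <- 1 / (layers_pred[[j]]$H * layers_pred[[j]]$W * layers_pred[[j]]$C)
    t_j <- tp_scale(tp, tp_frob2(tp, layers_pred[[j]]$node, layers_gt[[j]]$node$v), sc)
    lf <- if (is.null(lf)) t_j else tp_add(tp, lf, t_j)
    # per-sample values for the log
    nj <- layers_pred[[j]]$H * layers_pred[[j]]$W
    for (i in seq_len(B)) {
      rows <- (i - 1L) * nj + seq_len(nj)
      per_sample[i, 2L] <- per_sample[i, 2L] +
        sc * sum((layers_pred[[j]]$node$v[rows, ] - layers_gt[[j]]$node$v[rows, ])^2)
    }
  }
  l1 <- tp_charbonnier(tp, pred, gt_stack, weights$eps)
  for (i in seq_len(B)) {
    rows <- (i - 1L) * N + seq_len(N)
    d <- pred$v[rows, 1L] - gt_stack[rows, 1L]
    per_sample[i, 3L] <- sum(sqrt(d * d + weights$eps^2))
  }
  total <- tp_add(tp, total, tp_scale(tp, lf, weights$alpha2))
  total <- tp_add(tp, total, tp_scale(tp, l1, weights$alpha3))
  list(node = total, per_sample = per_sample)
}
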