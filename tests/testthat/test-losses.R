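# Loss module: Gram closed forms, style-balance sign behaviour, feature
# reconstruction, Charbonnier floor and the weighted total.

phi_id <- feature_network("identity")

clamp_mat <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

test_that("gram matrix closed forms", {
  expect_equal(gram_matrix(matrix(0, 3, 3)), matrix(0, 1, 1))
  # constant map of ones: every entry 1/C
  for (C in c(1L, 3L)) {
    f <- array(1, c(C, 4, 5))
    expect_equal(gram_matrix(f), matrix(1 / C, C, C))
  }
  # C = 1, 2x2 map [[0,2],[0,0]]: 4 / (1*2*2) = 1
  expect_equal(gram_matrix(matrix(c(0, 0, 2, 0), 2, 2)), matrix(1, 1, 1))
  expect_error(gram_matrix(array(0, c(1, 0, 2))), "empty")
})

test_that("style reconstruction loss: zero at equality, symmetric, hand value", {
  x <- matrix(runif(16), 4, 4)
  y <- matrix(runif(16), 4, 4)
  expect_equal(style_reconstruction_loss(x, x, phi_id), 0)
  expect_equal(style_reconstruction_loss(x, y, phi_id),
               style_reconstruction_loss(y, x, phi_id))
  # identity phi, x all ones, y all zeros (2x2): G_x = [[1]], G_y = [[0]]
  expect_equal(style_reconstruction_loss(matrix(1, 2, 2), matrix(0, 2, 2),
                                         phi_id), 1)
})

test_that("style balance loss vanishes at the optimum and flips its third term's sign", {
  f0 <- matrix(runif(16, 0.2, 0.4), 4, 4)
  gt <- matrix(runif(16, 0.4, 0.6), 4, 4)
  f2 <- matrix(runif(16, 0.6, 0.8), 4, 4)
  # pred == gt: all three signed terms are zero under sign(0) = 0
  r <- style_balance_loss(f0, gt, gt, f2, phi_id)
  expect_equal(r$value, 0)
  expect_equal(r$terms, c(0, 0, 0))
  # all four identical
  expect_equal(style_balance_loss(gt, gt, gt, gt, phi_id)$value, 0)

  # constructed fixtures on a 2x2 grid with identity phi: style distance is
  # (mean(x^2) - mean(y^2))^2, so it is controlled by image energy alone
  w <- loss_weights()
  mk <- function(v) matrix(v, 2, 2)
  f0 <- mk(0.1); gt <- mk(0.5); f2 <- mk(0.9)
  ls <- function(a, b) style_reconstruction_loss(a, b, phi_id)
  # pred farther from frame2 than gt is: sign +1, term = beta2 * L
  pred_far <- mk(0.3)
  r1 <- style_balance_loss(f0, gt, pred_far, f2, phi_id, w)
  expect_gt(ls(pred_far, f2), ls(gt, f2))
  expect_equal(r1$terms[3], w$beta[3] * ls(pred_far, f2))
  expect_gt(r1$terms[3], 0)
  # pred closer to frame2 than gt is: sign -1, term flips negative
  pred_near <- mk(0.8)
  r2 <- style_balance_loss(f0, gt, pred_near, f2, phi_id, w)
  expect_lt(ls(pred_near, f2), ls(gt, f2))
  expect_equal(r2$terms[3], -w$beta[3] * ls(pred_near, f2))
  expect_lt(r2$terms[3], 0)
  # brute-force scalar evaluation of the whole sum for the first fixture
  manual <- sum(vapply(1:3, function(j) {
    fr <- list(f0, gt, f2)[[j]]
    w$beta[j] * sign(ls(pred_far, fr) - ls(gt, fr)) * ls(pred_far, fr)
  }, 0))
  expect_equal(r1$value, manual)
})

test_that("feature reconstruction loss closed forms", {
  gt <- matrix(runif(16), 4, 4)
  expect_equal(feature_reconstruction_loss(gt, gt, phi_id), 0)
  # identity phi: mean squared error; constant difference 0.5 -> 0.25
  pred <- gt * 0 + 0.75
  base <- gt * 0 + 0.25
  expect_equal(feature_reconstruction_loss(pred, base, phi_id), 0.25)
  phi_c <- feature_network("convstack")
  for (s in 1:3) {
    a <- matrix(runif(64), 8, 8); b <- matrix(runif(64), 8, 8)
    expect_gte(feature_reconstruction_loss(a, b, phi_c), 0)
  }
})

test_that("charbonnier loss floor and direct values", {
  gt <- matrix(runif(4), 2, 2)
  expect_equal(charbonnier_loss(gt, gt), 4 * 1e-6)
  pred <- gt
  pred[1, 1] <- gt[1, 1] + 1
  expect_equal(charbonnier_loss(pred, gt), sqrt(1 + 1e-12) + 3e-6)
  for (s in 1:3) {
    a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
    expect_gte(charbonnier_loss(a, b), 16 * 1e-6)
  }
})

test_that("total loss composes its terms and honours weight degeneracies", {
  f0 <- matrix(runif(16), 4, 4); gt <- matrix(runif(16), 4, 4)
  f2 <- matrix(runif(16), 4, 4); pred <- matrix(runif(16), 4, 4)
  w <- loss_weights()
  r <- total_loss(f0, gt, pred, f2, phi_id, w)
  expect_equal(r$total, w$alpha1 * r$bs + w$alpha2 * r$f + w$alpha3 * r$l1,
               tolerance = 1e-9)
  # pred == gt: only the Charbonnier floor survives
  r0 <- total_loss(f0, gt, gt, f2, phi_id, w)
  expect_equal(r0$total, w$alpha3 * 16 * 1e-6)
  # alpha1 = alpha2 = 0 reduces to pure Charbonnier
  w2 <- loss_weights(alpha1 = 0, alpha2 = 0)
  r2 <- total_loss(f0, gt, pred, f2, phi_id, w2)
  expect_equal(r2$total, charbonnier_loss(pred, gt))
})

test_that("loss weight defaults match the training recipe", {
  w <- loss_weights()
  expect_equal(w$alpha1, 1e6)
  expect_equal(w$alpha2, 1)
  expect_equal(w$alpha3, 1)
  expect_equal(w$beta, c(0.1, 1, 0.1))
  expect_equal(w$eps, 1e-6)
})

test_that("batched tape loss agrees with the plain per-sample evaluation", {
  phi <- feature_network("convstack")
  w <- loss_weights()
  trips <- tiny_triplets(2, seed0 = 300L, size = 16L)
  # fake predictions: noisy copies of the ground truth
  set.seed(4)
  preds <- lapply(trips, function(s) clamp_mat(s$frames[[2]] + matrix(rnorm(256, sd = 0.05), 16, 16)))
  tp <- ssan:::tape_new()
  pred_stack <- ssan:::tp_const(tp, do.call(rbind, lapply(preds, function(p)
    matrix(as.vector(p), ncol = 1))))
  li <- ssan:::tp_total_loss_batch(tp, pred_stack, lapply(trips, `[[`, "frames"),
                                   phi, w, 16L, 16L)
  plain_total <- 0
  for (i in 1:2) {
    fr <- trips[[i]]$frames
    r <- total_loss(fr[[1]], fr[[2]], preds[[i]], fr[[3]], phi, w)
    plain_total <- plain_total + r$total
    expect_equal(unname(li$per_sample[i, "bs"]), r$bs, tolerance = 1e-9)
    expect_equal(unname(li$per_sample[i, "l1"]), r$l1, tolerance = 1e-9)
    expect_equal(unname(li$per_sample[i, "f"]), r$f, tolerance = 1e-9)
  }
  expect_equal(li$node$v, plain_total, tolerance = 1e-9)
})
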