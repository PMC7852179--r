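# The user-facing modelling interface: one fitting function returning a
# classed object with the usual methods.

#' Fit a slice-interpolation network
#'
#' Trains the sparse self-attention aggregation network to synthesize the
#' middle slice of serial-section triplets.  `data` may be a dataset
#' directory/manifest (from [generate_dataset()] or [build_dataset()]) or a
#' list of in-memory triplets.
#'
#' @param data triplet dataset: a manifest path, a manifest object, or a
#'   list of triplets (`$frames` = list of three `H x W` matrices in
#'   `[0, 1]`, optional `$split` in `train`/`val`/`test`).
#' @param model an [ssan_config()]; defaults to the `"tiny"` CPU preset.
#' @param train a [train_config()]; defaults to the `"desk"` schedule.
#' @param loss a [loss_weights()].
#' @param phi a [feature_network()] for the perceptual loss terms.
#' @param seed integer seed for weight initialization (training order and
#'   augmentation are governed by `train$seed`).
#' @param verbose print a line per epoch.
#' @return an object of class `"ssan"` with components `model` (best
#'   validation parameters), `final_model`, `history`, `step_log`,
#'   `gamma_trace` and the configurations; supports `print`, `summary`,
#'   `coef`, `predict` and `plot`.
#' @export
ssan_fit <- function(data, model = ssan_config(preset = "tiny"),
                     train = train_config(preset = "desk"),
                     loss = loss_weights(), phi = feature_network(),
                     seed = 1L, verbose = FALSE) {
  m0 <- ssan_init(model, seed = seed)
  res <- ssan_train(m0, data, tcfg = train, weights = loss, phi = phi,
                    verbose = verbose)
  structure(c(res, list(model_config = model, seed = seed,
                        call = match.call())),
            class = "ssan")
}

#' @export
print.ssan <- function(x, ...) {
  cfg <- x$model_config
  np <- sum(vapply(x$model$params, length, 0))
  cat("Sparse self-attention aggregation network (slice interpolation)\n")
  cat(sprintf("  backbone: RDN G0=%d, D=%d blocks x %d convs, growth %d -> C=%d channels\n",
              cfg$srdn$G0, cfg$srdn$D, cfg$srdn$convs_per_block, cfg$srdn$growth,
              cfg$srdn$C))
  cat(sprintf("  attention: %d-level, k=%d, level-1 partition (%s), level-2 (%s)\n",
              cfg$attention$levels, cfg$attention$k,
              paste(cfg$attention$level1, collapse = ","),
              paste(cfg$attention$level2, collapse = ",")))
  cat(sprintf("  parameters: %d   epochs trained: %d\n", np, nrow(x$history)))
  if (is.finite(x$best_val_psnr))
    cat(sprintf("  best validation PSNR: %.2f dB\n", x$best_val_psnr))
  invisible(x)
}

#' @export
summary.ssan <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  print(object)
  cat(sprintf("  loss: first epoch %.4g -> final epoch %.4g\n",
              h$loss[1L], h$loss[nrow(h)]))
  g <- coef(object)
  cat("  residual gates gamma:\n")
  for (n in names(g)) cat(sprintf("    %s = %+.5f\n", n, g[n]))
  invisible(list(history = h, gamma = g))
}

#' Residual-gate coefficients of the fitted network
#'
#' Returns the learnable `gamma` gates of the attention applications, the
#' only free scalars of the layer besides the projection matrices; they
#' start at 0 (pure residual path) and grow as the network learns to trust
#' non-local evidence.
#'
#' @param object a fitted `"ssan"` object.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.ssan <- function(object, ...) {
  g <- grep("^aal[0-9]+\\.gamma$", names(object$model$params), value = TRUE)
  stats::setNames(vapply(g, function(n) object$model$params[[n]][1L, 1L], 0), g)
}

#' Predict (interpolate) middle slices
#'
#' @param object a fitted `"ssan"` object.
#' @param f0,f2 a single frame pair (`H x W` matrices in `[0, 1]`).
#' @param newdata alternatively, a list of triplets or pairs; each element
#'   needs `$frames` (three frames, the middle one ignored) or `$f0`/`$f2`.
#' @param ... unused.
#' @return a single `H x W` matrix, or a list of them for `newdata`.
#' @export
predict.ssan <- function(object, f0 = NULL, f2 = NULL, newdata = NULL, ...) {
  if (!is.null(f0) && !is.null(f2)) return(ssan_predict_pair(object$model, f0, f2))
  if (is.null(newdata)) stop("supply either f0/f2 or newdata")
  lapply(newdata, function(s) {
    if (!is.null(s$frames)) ssan_predict_pair(object$model, s$frames[[1L]],
                                              s$frames[[length(s$frames)]])
    else ssan_predict_pair(object$model, s$f0, s$f2)
  })
}

#' Training diagnostics plot
#'
#' Left: per-epoch total loss (log scale) and validation PSNR; right: the
#' residual-gate trajectories, which start at zero and grow as the network
#' shifts weight onto the attention branch.
#'
#' @param x a fitted `"ssan"` object.
#' @param ... unused.
#' @export
plot.ssan <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", log = "y", xlab = "epoch",
                 ylab = "mean total loss", main = "training loss")
  gt <- x$gamma_trace
  graphics::matplot(seq_len(nrow(gt)), gt, type = "l", lty = 1,
                    xlab = "epoch", ylab = expression(gamma),
                    main = "residual gates")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Residuals of a fitted interpolation model
#'
#' Per-triplet difference images `prediction - ground truth`.
#'
#' @param object a fitted `"ssan"` object.
#' @param data triplets with ground-truth middle frames.
#' @param ... unused.
#' @return list of `H x W` residual matrices.
#' @export
residuals.ssan <- function(object, data, ...) {
  trips <- load_triplets(data)
  lapply(trips, function(s)
    ssan_predict_pair(object$model, s$frames[[1L]], s$frames[[3L]]) -
      quantize8(s$frames[[2L]]))
}
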