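# Training loop (Adam, staged learning-rate schedule, seeded augmentation),
# evaluation harness and the single-pair inference entry point.

#' Training configuration
#'
#' Defaults serialize the full training recipe: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, initial learning rate `1e-3` for 30
#' epochs followed by 20 epochs at a tenth of it, batch size 3.  The
#' `"desk"` preset shortens the schedule to 10 epochs at the initial rate
#' for CPU-scale runs; every override is recorded in the returned object.
#'
#' @param epochs integer vector: epochs per learning-rate stage.
#' @param lr initial learning rate.
#' @param lr_factor multiplicative decay applied at each stage boundary.
#' @param batch_size samples per optimization step.
#' @param beta1,beta2 Adam moment decays.
#' @param seed seed covering data order, augmentation and any stochastic
#'   choice of the loop.
#' @param augment apply random flips and temporal-order swaps.
#' @param preset `"paper"` (the full recipe) or `"desk"` (10 epochs).
#' @return object of class `"train_config"`.
#' @export
train_config <- function(epochs = NULL, lr = 1e-3, lr_factor = 0.1,
                         batch_size = 3L, beta1 = 0.9, beta2 = 0.999,
                         seed = 1L, augment = TRUE,
                         preset = c("paper", "desk")) {
  preset <- match.arg(preset)
  if (is.null(epochs)) epochs <- if (preset == "desk") c(10L) else c(30L, 20L)
  structure(list(epochs = as.integer(epochs), lr = lr, lr_factor = lr_factor,
                 batch_size = as.integer(batch_size), beta1 = beta1,
                 beta2 = beta2, seed = as.integer(seed), augment = augment,
                 preset = preset),
            class = "train_config")
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 / (1 - b1^st$t); c2 <- 1 / (1 - b2^st$t)
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g * g
    params[[k]] <- params[[k]] - lr * (st$m[[k]] * c1) / (sqrt(st$v[[k]] * c2) + eps)
  }
  list(params = params, state = st)
}

# Load triplets referenced by a manifest (as written by generate_dataset or
# build_dataset); `data` may also already be a list of triplets.
load_triplets <- function(data) {
  if (is.list(data) && !is.null(data$samples)) {
    dir <- attr(data, "dir")
    if (is.null(dir)) stop("manifest lists files but carries no 'dir' attribute")
    return(lapply(data$samples, function(s)
      list(frames = lapply(file.path(dir, unlist(s$files)), read_slice),
           split = s$split, id = s$id)))
  }
  if (is.character(data) && length(data) == 1L) {
    mpath <- if (dir.exists(data)) file.path(data, "manifest.json") else data
    man <- jsonlite::read_json(mpath)
    attr(man, "dir") <- dirname(mpath)
    return(load_triplets(man))
  }
  lapply(data, function(s) {
    if (inherits(s, "synthetic_triplet")) list(frames = s$frames, split = "train", id = NA)
    else if (!is.null(s$frames)) s
    else stop("unrecognized triplet data")
  })
}

#' Train the interpolation network
#'
#' Runs the end-to-end pipeline per step — siamese feature extraction,
#' attention warp synthesis for both directions, mask fusion, total loss —
#' and optimizes all parameters with Adam.  Logs per-epoch mean loss terms
#' (including the three signed style-balance components), the residual-gate
#' values, and validation PSNR; the best-validation-PSNR parameters are
#' kept.  Fully seeded: identical seeds give identical runs.
#'
#' @param model an `"ssan_model"` from [ssan_init()].
#' @param data manifest path/object or list of triplets (each with
#'   `$frames`, a list of three `H x W` matrices in `[0, 1]`, and
#'   optionally `$split`).
#' @param tcfg a [train_config()].
#' @param weights a [loss_weights()].
#' @param phi a [feature_network()] for the perceptual terms.
#' @param verbose print a line per epoch.
#' @return list with the trained `model` (best-validation parameters),
#'   `final_model` (last-epoch parameters), `history` (per-epoch data
#'   frame), `step_log` (per-step loss terms), `gamma_trace` (epoch x gate
#'   matrix) and configuration echoes.
#' @export
ssan_train <- function(model, data, tcfg = train_config(preset = "desk"),
                       weights = loss_weights(), phi = feature_network(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "ssan_model"), inherits(tcfg, "train_config"))
  trips <- load_triplets(data)
  splits <- vapply(trips, function(s) if (is.null(s$split)) "train" else s$split, "")
  train_ids <- which(splits == "train")
  val_ids <- which(splits == "val")
  if (length(train_ids) == 0L) stop("empty training split")
  H <- nrow(trips[[1L]]$frames[[1L]]); W <- ncol(trips[[1L]]$frames[[1L]])
  check_partition(H, W, model$cfg$attention)

  params <- model$params
  opt <- adam_new(params)
  gamma_names <- grep("^aal[0-9]+\\.gamma$", names(params), value = TRUE)
  n_epochs <- sum(tcfg$epochs)
  lr_of_epoch <- rep(tcfg$lr * tcfg$lr_factor^(seq_along(tcfg$epochs) - 1L), tcfg$epochs)
  history <- vector("list", n_epochs)
  step_log <- list()
  gamma_trace <- matrix(NA_real_, n_epochs, length(gamma_names),
                        dimnames = list(NULL, gamma_names))
  best <- list(psnr = -Inf, params = params, bn_mean = model$state$bn_mean,
               bn_var = model$state$bn_var)

  old_rng <- get_rng_state(); on.exit(set_rng_state(old_rng))
  set.seed(tcfg$seed)
  gstep <- 0L
  for (ep in seq_len(n_epochs)) {
    ord <- sample(train_ids)
    nbat <- ceiling(length(ord) / tcfg$batch_size)
    ep_terms <- matrix(0, 0L, 7L)
    for (b in seq_len(nbat)) {
      ids <- ord[((b - 1L) * tcfg$batch_size + 1L):min(b * tcfg$batch_size, length(ord))]
      batch <- lapply(ids, function(i) {
        fr <- trips[[i]]$frames
        if (tcfg$augment) fr <- augment_sample(fr, seed = sample.int(2^30, 1L))$frames
        fr
      })
      model$params <- params
      tp <- tape_new()
      lv <- make_leaves(tp, params)
      fwd <- ssan_forward_batch(tp, lv, model,
                                lapply(batch, function(fr) list(f0 = fr[[1L]], f2 = fr[[3L]])),
                                train = TRUE)
      li <- tp_total_loss_batch(tp, fwd$pred, batch, phi, weights, H, W)
      terms <- li$per_sample
      tot <- tp_scale(tp, li$node, 1 / length(batch))
      if (!is.finite(tot$v))
        stop(sprintf("NaN/Inf loss at epoch %d step %d; loss terms: %s",
                     ep, b, paste(signif(colMeans(terms), 4), collapse = " ")))
      tape_backward(tp, tot)
      grads <- lapply(lv, function(nd) nd$g)
      upd <- adam_step(params, grads, opt, lr_of_epoch[ep], tcfg$beta1, tcfg$beta2)
      params <- upd$params; opt <- upd$state
      gstep <- gstep + 1L
      step_log[[gstep]] <- c(epoch = ep, step = gstep, total = tot$v,
                             bs = mean(terms[, 1L]), f = mean(terms[, 2L]),
                             l1 = mean(terms[, 3L]),
                             sign0 = mean(terms[, 4L]), sign1 = mean(terms[, 5L]),
                             sign2 = mean(terms[, 6L]))
      ep_terms <- rbind(ep_terms, c(tot$v, colMeans(terms)))
    }
    model$params <- params
    val_psnr <- NA_real_
    if (length(val_ids) > 0L) {
      preds <- ssan_predict_pairs(model, lapply(val_ids, function(i)
        list(f0 = trips[[i]]$frames[[1L]], f2 = trips[[i]]$frames[[3L]])))
      val_psnr <- mean(vapply(seq_along(val_ids), function(k) {
        compute_metrics(preds[[k]], quantize8(trips[[val_ids[k]]]$frames[[2L]]))$psnr
      }, 0))
      if (is.finite(val_psnr) && val_psnr > best$psnr)
        best <- list(psnr = val_psnr, params = params,
                     bn_mean = model$state$bn_mean, bn_var = model$state$bn_var)
    }
    gamma_trace[ep, ] <- vapply(gamma_names, function(g) params[[g]][1L, 1L], 0)
    history[[ep]] <- data.frame(epoch = ep, lr = lr_of_epoch[ep],
                                loss = mean(ep_terms[, 1L]), bs = mean(ep_terms[, 2L]),
                                f = mean(ep_terms[, 3L]), l1 = mean(ep_terms[, 4L]),
                                sign0 = mean(ep_terms[, 5L]), sign1 = mean(ep_terms[, 6L]),
                                sign2 = mean(ep_terms[, 7L]), val_psnr = val_psnr)
    if (verbose)
      message(sprintf("epoch %2d  lr %.1e  loss %.4g  val PSNR %.2f dB",
                      ep, lr_of_epoch[ep], mean(ep_terms[, 1L]), val_psnr))
  }
  final_model <- model
  final_model$params <- params
  best_model <- model
  if (is.finite(best$psnr)) {
    best_model$params <- best$params
    best_model$state <- new.env(parent = emptyenv())
    best_model$state$bn_mean <- best$bn_mean
    best_model$state$bn_var <- best$bn_var
  } else best_model$params <- params
  list(model = best_model, final_model = final_model,
       history = do.call(rbind, history),
       step_log = as.data.frame(do.call(rbind, step_log)),
       gamma_trace = gamma_trace, best_val_psnr = best$psnr,
       train_config = tcfg, loss_weights = weights)
}

#' Evaluate a model on a triplet set
#'
#' Interpolates the middle frame of every triplet and reports per-sample
#' and mean PSNR/SSIM/IE, alongside two input-only baselines: the per-pixel
#' average of the two input frames and frame 0 copied unchanged.
#'
#' @param model an `"ssan_model"` or fitted [ssan_fit()] object.
#' @param data manifest or list of triplets (see [ssan_train()]).
#' @param split evaluate only samples of this split (`NULL` for all).
#' @return object of class `"ssan_metrics"`: per-sample data frame and the
#'   mean table.
#' @export
evaluate_model <- function(model, data, split = "test") {
  model <- as_ssan_model(model)
  trips <- load_triplets(data)
  if (!is.null(split)) {
    keep <- vapply(trips, function(s) identical(s$split, split), TRUE)
    if (any(keep)) trips <- trips[keep]
  }
  if (length(trips) == 0L) stop("no samples to evaluate")
  preds <- ssan_predict_pairs(model, lapply(trips, function(s)
    list(f0 = s$frames[[1L]], f2 = s$frames[[3L]])))
  rows <- lapply(seq_along(trips), function(i) {
    fr <- trips[[i]]$frames
    gt <- quantize8(fr[[2L]])
    pred <- preds[[i]]
    avg <- clamp01((fr[[1L]] + fr[[3L]]) / 2)
    mo <- compute_metrics(pred, gt)
    ma <- compute_metrics(avg, gt)
    mc <- compute_metrics(fr[[1L]], gt)
    data.frame(sample = i,
               psnr = mo$psnr, ssim = mo$ssim, ie = mo$ie,
               psnr_avg = ma$psnr, ssim_avg = ma$ssim, ie_avg = ma$ie,
               psnr_copy = mc$psnr, ssim_copy = mc$ssim, ie_copy = mc$ie)
  })
  per_sample <- do.call(rbind, rows)
  means <- colMeans(per_sample[, -1L])
  structure(list(per_sample = per_sample, means = means, n = nrow(per_sample)),
            class = "ssan_metrics")
}

#' @export
print.ssan_metrics <- function(x, ...) {
  cat(sprintf("interpolation metrics over %d samples:\n", x$n))
  m <- x$means
  cat(sprintf("  model            PSNR %6.2f dB  SSIM %6.4f  IE %6.2f\n",
              m["psnr"], m["ssim"], m["ie"]))
  cat(sprintf("  average-of-inputs PSNR %6.2f dB  SSIM %6.4f  IE %6.2f\n",
              m["psnr_avg"], m["ssim_avg"], m["ie_avg"]))
  cat(sprintf("  copy-frame-0      PSNR %6.2f dB  SSIM %6.4f  IE %6.2f\n",
              m["psnr_copy"], m["ssim_copy"], m["ie_copy"]))
  invisible(x)
}

#' Interpolate the slice between two images
#'
#' @param model an `"ssan_model"` or fitted [ssan_fit()] object.
#' @param a,b same-shaped grayscale images in `[0, 1]`, or paths readable
#'   by [read_slice()].
#' @param out optional output PNG path; when given, the synthesized slice
#'   is written as 8-bit grayscale.
#' @return the synthesized `H x W` image (after 8-bit quantization if
#'   written), invisibly when `out` is given.
#' @export
interpolate_pair <- function(model, a, b, out = NULL) {
  model <- as_ssan_model(model)
  if (is.character(a)) a <- read_slice(a)
  if (is.character(b)) b <- read_slice(b)
  pred <- ssan_predict_pair(model, a, b)
  if (!is.null(out)) {
    write_slice(pred, out)
    return(invisible(quantize8(pred)))
  }
  pred
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a schema version; batch-norm running
#' statistics are included.
#'
#' @param model an `"ssan_model"` or fitted [ssan_fit()] object.
#' @param path file path.
#' @return `ssan_save` returns the path invisibly; `ssan_load` the restored
#'   object.
#' @export
ssan_save <- function(model, path) {
  obj <- if (inherits(model, "ssan")) {
    list(kind = "ssan_fit", version = 1L, fit = strip_fit(model))
  } else {
    m <- as_ssan_model(model)
    list(kind = "ssan_model", version = 1L,
         model = list(params = m$params, cfg = m$cfg, seed = m$seed,
                      bn_mean = m$state$bn_mean, bn_var = m$state$bn_var))
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname ssan_save
#' @export
ssan_load <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$kind) || is.null(obj$version))
    stop("not an ssan checkpoint")
  if (obj$kind == "ssan_model") {
    st <- new.env(parent = emptyenv())
    st$bn_mean <- obj$model$bn_mean
    st$bn_var <- obj$model$bn_var
    structure(list(params = obj$model$params, cfg = obj$model$cfg,
                   state = st, seed = obj$model$seed, schema_version = obj$version),
              class = "ssan_model")
  } else if (obj$kind == "ssan_fit") {
    fit <- obj$fit
    fit$model <- restore_model(fit$model)
    fit$final_model <- restore_model(fit$final_model)
    fit
  } else stop(sprintf("unknown checkpoint kind '%s'", obj$kind))
}

strip_fit <- function(fit) {
  flat <- function(m) list(params = m$params, cfg = m$cfg, seed = m$seed,
                           bn_mean = m$state$bn_mean, bn_var = m$state$bn_var)
  fit$model <- flat(fit$model)
  fit$final_model <- flat(fit$final_model)
  fit
}

restore_model <- function(flat) {
  st <- new.env(parent = emptyenv())
  st$bn_mean <- flat$bn_mean
  st$bn_var <- flat$bn_var
  structure(list(params = flat$params, cfg = flat$cfg, state = st,
                 seed = flat$seed, schema_version = 1L),
            class = "ssan_model")
}
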