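# Training harness: configuration snapshot, seeded reproducibility,
# checkpointing, evaluation baselines and the inference entry point.

micro_fit <- function(trips, seed = 1L, epochs = 2L) {
  cfg <- ssan_config(srdn = srdn_config(G0 = 4, D = 1, convs_per_block = 1,
                                        growth = 4, C = 4),
                     attention = attention_config(k = 2, level1 = c(2, 2, 8, 8),
                                                  level2 = c(2, 2, 4, 4)),
                     fusion_width = 4)
  ssan_fit(trips, model = cfg,
           train = train_config(epochs = epochs, batch_size = 3L,
                                preset = "desk", seed = seed),
           seed = seed)
}

test_that("the default training configuration serializes the full recipe", {
  tc <- train_config()
  expect_equal(tc$epochs, c(30L, 20L))
  expect_equal(tc$lr, 1e-3)
  expect_equal(tc$lr_factor, 0.1)
  expect_equal(tc$batch_size, 3L)
  expect_equal(tc$beta1, 0.9)
  expect_equal(tc$beta2, 0.999)
  expect_identical(tc$preset, "paper")
  # the desk preset is an explicit, logged override
  td <- train_config(preset = "desk")
  expect_equal(sum(td$epochs), 10L)
  expect_identical(td$preset, "desk")
})

test_that("identical seeds reproduce the run; gates start at zero and are traced", {
  trips <- tiny_triplets(6, seed0 = 700L, size = 16L)
  f1 <- micro_fit(trips, seed = 5L)
  f2 <- micro_fit(trips, seed = 5L)
  expect_equal(f1$history$loss, f2$history$loss, tolerance = 1e-6)
  expect_identical(coef(f1), coef(f2))
  # gamma trace exists for every epoch and every gate, starting from 0
  expect_equal(dim(f1$gamma_trace), c(2L, 3L))
  m0 <- ssan_init(f1$model_config, seed = 5L)
  expect_true(all(vapply(grep("^aal[0-9]+\\.gamma$", names(m0$params), value = TRUE),
                         function(g) m0$params[[g]][1, 1] == 0, TRUE)))
  # step log carries the three signed style-balance terms
  expect_true(all(c("sign0", "sign1", "sign2") %in% names(f1$step_log)))
})

test_that("training aborts with a diagnostic on non-finite loss", {
  trips <- tiny_triplets(3, seed0 = 710L, size = 16L)
  cfg <- ssan_config(srdn = srdn_config(G0 = 4, D = 1, convs_per_block = 1,
                                        growth = 4, C = 4),
                     attention = attention_config(k = 2, level1 = c(2, 2, 8, 8),
                                                  level2 = c(2, 2, 4, 4)),
                     fusion_width = 4)
  m <- ssan_init(cfg, seed = 1L)
  m$params[["head.w"]][] <- 1e308   # force overflow in the first forward
  expect_error(ssan_train(m, trips, train_config(epochs = 1L, preset = "desk")),
               "NaN|Inf")
  expect_error(ssan_train(ssan_init(cfg, 1L),
                          lapply(trips, function(s) { s$split <- "test"; s }),
                          train_config(epochs = 1L, preset = "desk")),
               "empty training split")
})

test_that("evaluation reports model and baseline metrics with sane bounds", {
  trips <- tiny_triplets(4, seed0 = 720L, size = 16L,
                         split = rep("test", 4))
  fit <- micro_fit(lapply(tiny_triplets(6, 730L, 16L), identity), epochs = 1L)
  ev <- evaluate_model(fit, trips, split = "test")
  expect_equal(ev$n, 4L)
  expect_true(all(c("psnr", "psnr_avg", "psnr_copy") %in% names(ev$means)))
  expect_true(all(ev$per_sample$ssim <= 1 & ev$per_sample$ssim >= -1))
  expect_true(all(ev$per_sample$ie >= 0))
})

test_that("ground truth as prediction attains the metric upper bound", {
  tr <- generate_triplet(synthetic_config(size = c(16L, 16L), seed = 741L))
  gt <- ssan:::quantize8(tr$frames[[2]])
  m <- compute_metrics(gt, gt)
  expect_equal(m$ie, 0)
  expect_equal(m$ssim, 1)
})

test_that("checkpoints round-trip through save/load and predict identically", {
  trips <- tiny_triplets(6, seed0 = 750L, size = 16L)
  fit <- micro_fit(trips, epochs = 1L)
  path <- withr::local_tempfile(fileext = ".rds")
  ssan_save(fit, path)
  back <- ssan_load(path)
  a <- trips[[1]]$frames[[1]]; b <- trips[[1]]$frames[[3]]
  expect_identical(predict(fit, a, b), predict(back, a, b))
  bogus <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bogus)
  expect_error(ssan_load(bogus))
})

test_that("interpolate_pair writes an 8-bit PNG that round-trips exactly", {
  trips <- tiny_triplets(6, seed0 = 760L, size = 16L)
  fit <- micro_fit(trips, epochs = 1L)
  a <- trips[[1]]$frames[[1]]; b <- trips[[1]]$frames[[3]]
  out <- withr::local_tempfile(fileext = ".png")
  img <- interpolate_pair(fit, a, b, out = out)
  expect_identical(read_slice(out), img)
  # repeated calls are bit-identical
  p1 <- interpolate_pair(fit, a, b)
  p2 <- interpolate_pair(fit, a, b)
  expect_identical(p1, p2)
  # degenerate equal inputs stay within the convex envelope at any stage
  pe <- interpolate_pair(fit, a, a)
  expect_true(all(is.finite(pe)))
})

test_that("yaml config maps onto the constructors", {
  cfgfile <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model:", "  preset: tiny", "  channels: 8", "  k: 2",
               "  level1: [2, 2, 8, 8]", "  level2: [2, 2, 4, 4]",
               "loss:", "  alpha: [1.0e6, 1, 1]", "  phi: identity",
               "train:", "  preset: desk", "  epochs: [3]", "  seed: 9"),
             cfgfile)
  cc <- ssan_read_config(cfgfile)
  expect_equal(cc$model$srdn$C, 8L)
  expect_equal(cc$model$attention$level1, c(2L, 2L, 8L, 8L))
  expect_equal(cc$loss$alpha1, 1e6)
  expect_identical(cc$phi$variant, "identity")
  expect_equal(cc$train$epochs, 3L)
  expect_equal(cc$train$seed, 9L)
})

test_that("fitted object methods: print, summary, coef, residuals", {
  trips <- tiny_triplets(6, seed0 = 770L, size = 16L)
  fit <- micro_fit(trips, epochs = 1L)
  expect_output(print(fit), "attention")
  expect_output(summary(fit), "gamma")
  expect_length(coef(fit), 3L)
  res <- residuals(fit, trips[1:2])
  expect_length(res, 2L)
  expect_equal(dim(res[[1]]), c(16L, 16L))
})
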