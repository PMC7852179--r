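# Dataset construction: alignment, grid cropping, quality filtering,
# histogram specification, augmentation and the end-to-end builder.

mk_texture <- function(seed, size = 64L) {
  generate_base_texture(synthetic_config(size = c(size, size), seed = seed))
}

test_that("alignment recovers constructed integer shifts exactly", {
  base <- mk_texture(51)
  # self-match: zero offset, NCC 1
  r0 <- align_triplet(list(base, base, base), search_radius = 5)
  expect_equal(unname(r0$offsets), matrix(0L, 2, 2))
  expect_equal(r0$ncc, c(1, 1), tolerance = 1e-12)
  expect_false(r0$failed)

  # frame 0 = frame 1 shifted by (+3, -2): recovered correction (-3, +2)
  shifted <- ssan:::shift_int(base, 3L, -2L)
  shifted[is.na(shifted)] <- 0.5
  r <- align_triplet(list(shifted, base, base), search_radius = 5)
  expect_equal(unname(r$offsets["frame0", ]), c(-3L, 2L))
  # aligned frame agrees with the reference on the common crop
  expect_lt(max(abs(r$frames[[1]] - r$frames[[2]])), 1e-12)

  # independent white noise: NCC near zero, failure flag raised
  set.seed(52)
  n1 <- matrix(runif(64 * 64), 64, 64)
  n2 <- matrix(runif(64 * 64), 64, 64)
  rn <- align_triplet(list(n1, n2, n2), search_radius = 3)
  expect_true(rn$failed)
})

test_that("grid cropping counts follow floor((dim - crop) / stride) + 1", {
  mk <- function(H, W) {
    f <- matrix(runif(H * W), H, W)
    list(f, f, f)
  }
  expect_length(crop_grid(mk(3072, 3072), 512, 512), 36L)
  expect_length(crop_grid(mk(1024, 1024), 512, 512), 4L)
  s1 <- crop_grid(mk(512, 512), 512, 512)
  expect_length(s1, 1L)
  expect_equal(unname(s1[[1]]$origin), c(0L, 0L))
  expect_length(crop_grid(mk(100, 100), 512, 512), 0L)
  # half-open windows trace back to source pixels (no resampling)
  big <- mk(64, 64)
  cr <- crop_grid(big, 32, 32)
  expect_identical(cr[[2]]$frames[[1]],
                   big[[1]][cr[[2]]$origin["row"] + 1:32, cr[[2]]$origin["col"] + 1:32])
})

test_that("quality filter rejects the constructed defect and blur cases", {
  tr <- generate_triplet(synthetic_config(seed = 61L))$frames
  th <- quality_thresholds()
  ok <- quality_filter(tr, th)
  expect_true(ok$pass)
  expect_named(ok$scores, c("defect_fraction", "continuity_ncc", "blur_ratio"))

  # 40% of the middle frame zeroed: defect rule (default max 0.1)
  bad <- tr
  z <- bad[[2]]
  z[1:nrow(z), 1:floor(0.4 * ncol(z))] <- 0
  bad[[2]] <- z
  r <- quality_filter(bad, th)
  expect_false(r$pass)
  expect_gt(r$scores["defect_fraction"], th$defect_fraction_max)

  # middle frame blurred at sigma 4 while neighbours stay sharp: blur rule
  blurred <- tr
  blurred[[2]] <- ssan:::gaussian_blur(tr[[2]], 4)
  rb <- quality_filter(blurred, th)
  expect_false(rb$pass)
  expect_gt(rb$scores["blur_ratio"], th$blur_ratio_max)

  # uncorrelated middle frame: continuity rule
  set.seed(62)
  rnd <- tr
  rnd[[2]] <- matrix(runif(length(tr[[2]])), nrow(tr[[2]]))
  expect_false(quality_filter(rnd, th)$pass)
})

test_that("histogram specification matches CDFs and inverts monotone transforms", {
  tr <- generate_triplet(synthetic_config(seed = 71L))$frames
  # identical frames: no-op
  same <- histogram_specification(list(tr[[2]], tr[[2]], tr[[2]]))
  expect_equal(same[[1]], ssan:::quantize8(tr[[2]]), tolerance = 1 / 255)

  # gamma-transformed copy is recovered to within 2 gray levels; gamma is
  # kept mild enough that 8-bit quantization does not collapse distinct
  # dark levels, which no remapping could undo
  base <- ssan:::quantize8(mk_texture(72))
  gam <- base^1.3
  out <- histogram_specification(list(gam, base, base))
  expect_lte(max(abs(round(out[[1]] * 255) - round(base * 255))), 2)

  # KS distance to the reference CDF decreases for random fixtures
  for (s in 1:3) {
    a <- ssan:::quantize8(mk_texture(80 + s)^1.5)
    b <- ssan:::quantize8(mk_texture(90 + s))
    ks <- function(x, y) {
      cx <- cumsum(tabulate(round(x * 255) + 1L, 256L)) / length(x)
      cy <- cumsum(tabulate(round(y * 255) + 1L, 256L)) / length(y)
      max(abs(cx - cy))
    }
    matched <- histogram_specification(list(a, b, b))[[1]]
    expect_lt(ks(matched, b), ks(a, b))
  }

  # constant reference: flagged no-op
  flat <- matrix(0.5, 16, 16)
  r <- histogram_specification(list(mk_texture(99, 16), flat, flat))
  expect_true(attr(r, "constant_reference"))
})

test_that("augmentation is an involution per flip, swap-invariant in the middle, seeded", {
  tr <- generate_triplet(synthetic_config(seed = 81L))$frames
  a1 <- augment_sample(tr, seed = 4L)
  a2 <- augment_sample(tr, seed = 4L)
  expect_identical(a1$frames, a2$frames)
  # applying the same flips twice restores the original
  d <- a1$decisions
  undo <- a1$frames
  if (d$temporal_swap) undo <- undo[c(3, 2, 1)]
  undo <- lapply(undo, function(f) {
    if (d$hflip) f <- f[, rev(seq_len(ncol(f)))]
    if (d$vflip) f <- f[rev(seq_len(nrow(f))), ]
    f
  })
  expect_identical(undo, tr)
  # a seed that swaps temporal order leaves the middle frame fixed
  found <- FALSE
  for (s in 1:20) {
    a <- augment_sample(tr, seed = s)
    if (a$decisions$temporal_swap && !a$decisions$hflip && !a$decisions$vflip) {
      expect_identical(a$frames[[2]], tr[[2]])
      expect_identical(a$frames[[1]], tr[[3]])
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("build_dataset assembles, filters and splits by slice blocks", {
  # synthetic 5-slice volume of 64x64 without defects: 3 triples x 4 crops
  base <- mk_texture(91)
  set.seed(92)
  slices <- lapply(0:4, function(k) {
    # same section content with mild per-slice noise; no net drift, so the
    # full frame survives alignment and the crop arithmetic is exact
    ssan:::quantize8(base + matrix(rnorm(64 * 64, sd = 0.005), 64, 64))
  })
  vol <- slice_volume(slices)
  out <- withr::local_tempdir()
  man <- build_dataset(vol, out, crop = 32L, stride = 32L, search_radius = 3L)
  expect_equal(man$n, 12L)
  expect_length(list.files(out, pattern = "png$"), 36L)

  # idempotence: byte-identical manifests and images on a re-run
  out2 <- withr::local_tempdir()
  build_dataset(vol, out2, crop = 32L, stride = 32L, search_radius = 3L)
  m1 <- readLines(file.path(out, "manifest.json"))
  m2 <- readLines(file.path(out2, "manifest.json"))
  expect_identical(m1, m2)

  # split disjointness by middle-slice index
  sl <- vapply(man$samples, `[[`, 0L, "slice")
  sp <- vapply(man$samples, `[[`, "", "split")
  expect_true(all(vapply(split(sp, sl), function(x) length(unique(x)) == 1L, TRUE)))

  # an all-black slice causes its triples to be rejected with recorded reasons
  slices_bad <- slices
  slices_bad[[3]] <- matrix(0, 64, 64)
  manb <- build_dataset(slice_volume(slices_bad), withr::local_tempdir(),
                        crop = 32L, stride = 32L, search_radius = 3L)
  expect_gt(length(manb$failures), 0L)
  touched <- vapply(manb$samples, `[[`, 0L, "slice")
  expect_false(any(touched %in% 2:4))   # all triples touching slice 3 fail

  expect_error(build_dataset(slice_volume(slices[1:2]), withr::local_tempdir()),
               "at least 3")
})
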