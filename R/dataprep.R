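# Triplet dataset construction from real serial-section volumes: template
# matching alignment, stride-grid cropping, quality filtering, histogram
# specification, and a leakage-free 3:1:1 split by slice index.

#' Quality-filter thresholds
#'
#' The deletion rules for damaged samples, each with an explicit measurable
#' stand-in: saturated/zero-pixel fraction (defects), minimum consecutive
#' -frame normalized cross-correlation (weak continuity), and the ratio of
#' Laplacian variances between the sharpest and blurriest frame
#' (substantial blur differences).
#'
#' @param defect_fraction_max maximum tolerated fraction of pixels at 0 or
#'   255 (on the 8-bit grid) in any frame.
#' @param continuity_ncc_min minimum NCC between consecutive frames.
#' @param blur_ratio_max maximum sharpest/blurriest Laplacian-variance ratio.
#' @return object of class `"quality_thresholds"`.
#' @export
quality_thresholds <- function(defect_fraction_max = 0.1,
                               continuity_ncc_min = 0.2,
                               blur_ratio_max = 3.0) {
  stopifnot(defect_fraction_max >= 0, defect_fraction_max <= 1,
            continuity_ncc_min >= -1, continuity_ncc_min <= 1,
            blur_ratio_max >= 1)
  structure(list(defect_fraction_max = defect_fraction_max,
                 continuity_ncc_min = continuity_ncc_min,
                 blur_ratio_max = blur_ratio_max),
            class = "quality_thresholds")
}

# Integer translation of an image: content moves by (dy, dx); out-of-range
# pixels are NA (cropped away by the caller).  No resampling.
shift_int <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  rs <- seq_len(H) - dy; cs <- seq_len(W) - dx
  rok <- rs >= 1L & rs <= H; cok <- cs >= 1L & cs <= W
  out[which(rok), which(cok)] <- img[rs[rok], cs[cok]]
  out
}

#' Align a triplet by template matching
#'
#' A central template (half the frame in each dimension) is taken from the
#' middle frame and matched against frames 0 and 2 over all integer
#' translations within `search_radius`, maximizing normalized
#' cross-correlation.  The outer frames are translated by the recovered
#' correction offsets and all three frames are cropped to the common valid
#' region.  Translation only: no pixel is fabricated by resampling.
#'
#' @param frames list of three same-shaped grayscale matrices.
#' @param search_radius maximum |offset| searched per axis, pixels; must be
#'   below a quarter of the frame size.
#' @param ncc_floor matches with best NCC below this raise the failure flag.
#' @return list with `offsets` (2 x 2 matrix, correction `(dy, dx)` for
#'   frames 0 and 2), `ncc` (their best scores), `frames` (aligned and
#'   cropped), and `failed`.
#' @export
align_triplet <- function(frames, search_radius = 10L, ncc_floor = 0.2) {
  stopifnot(length(frames) == 3L)
  check_same_shape(frames[[1L]], frames[[2L]])
  check_same_shape(frames[[2L]], frames[[3L]])
  H <- nrow(frames[[2L]]); W <- ncol(frames[[2L]])
  r <- as.integer(search_radius)
  if (r >= min(H, W) / 4) stop("search_radius must be below a quarter of the frame size")
  th <- H %/% 4L; tw <- W %/% 4L
  trows <- (th + 1L):(H - th); tcols <- (tw + 1L):(W - tw)
  tmpl <- as.vector(frames[[2L]][trows, tcols])
  match_one <- function(img) {
    best <- c(0L, 0L); best_ncc <- -Inf
    for (dx in -r:r) for (dy in -r:r) {
      win <- img[trows + dy, tcols + dx]
      ncc <- suppressWarnings(stats::cor(tmpl, as.vector(win)))
      if (!is.na(ncc) && ncc > best_ncc) { best_ncc <- ncc; best <- c(dy, dx) }
    }
    list(shift = best, ncc = best_ncc)
  }
  m0 <- match_one(frames[[1L]])
  m2 <- match_one(frames[[3L]])
  offsets <- rbind(-m0$shift, -m2$shift)
  rownames(offsets) <- c("frame0", "frame2")
  colnames(offsets) <- c("dy", "dx")
  ncc <- c(m0$ncc, m2$ncc)
  failed <- any(ncc < ncc_floor)
  a0 <- shift_int(frames[[1L]], offsets[1L, 1L], offsets[1L, 2L])
  a2 <- shift_int(frames[[3L]], offsets[2L, 1L], offsets[2L, 2L])
  # common valid rectangle implied by the two translations
  rlo <- 1L + max(0L, offsets[, 1L]); rhi <- H + min(0L, offsets[, 1L])
  clo <- 1L + max(0L, offsets[, 2L]); chi <- W + min(0L, offsets[, 2L])
  crop <- function(x) x[rlo:rhi, clo:chi, drop = FALSE]
  list(offsets = offsets, ncc = ncc, failed = failed,
       frames = list(crop(a0), crop(frames[[2L]]), crop(a2)))
}

#' Grid cropping of an aligned triplet
#'
#' Crops windows at rows/columns `0, stride, 2*stride, ...` (0-based,
#' top-left origin, half-open windows) while the window fits;
#' `floor((dim - crop) / stride) + 1` crops per dimension.  Frames smaller
#' than the crop yield an empty list.
#'
#' @param frames list of three aligned same-shaped matrices.
#' @param crop window size in pixels.
#' @param stride step between window origins.
#' @return list of samples, each `list(frames, origin = c(row, col))` with
#'   0-based origins.
#' @export
crop_grid <- function(frames, crop = 512L, stride = 512L) {
  H <- nrow(frames[[1L]]); W <- ncol(frames[[1L]])
  if (H < crop || W < crop) return(list())
  r0 <- seq(0L, H - crop, by = stride)
  c0 <- seq(0L, W - crop, by = stride)
  out <- vector("list", length(r0) * length(c0))
  i <- 0L
  for (rr in r0) for (cc in c0) {
    i <- i + 1L
    out[[i]] <- list(frames = lapply(frames, function(f)
      f[rr + seq_len(crop), cc + seq_len(crop), drop = FALSE]),
      origin = c(row = rr, col = cc))
  }
  out
}

#' Quality filter for a triplet sample
#'
#' Pure predicate: fails on defect fraction, weak continuity or blur
#' imbalance; all three scores are always reported.
#'
#' @param frames list of three same-shaped matrices in `[0, 1]`.
#' @param thresholds a [quality_thresholds()].
#' @return list with `pass` and `scores` (`defect_fraction`,
#'   `continuity_ncc`, `blur_ratio`).
#' @export
quality_filter <- function(frames, thresholds = quality_thresholds()) {
  defect <- max(vapply(frames, function(f) {
    g <- round(f * 255)
    mean(g <= 0 | g >= 255)
  }, 0))
  ncc01 <- suppressWarnings(stats::cor(as.vector(frames[[1L]]), as.vector(frames[[2L]])))
  ncc12 <- suppressWarnings(stats::cor(as.vector(frames[[2L]]), as.vector(frames[[3L]])))
  ncc <- min(ncc01, ncc12, na.rm = FALSE)
  if (is.na(ncc)) ncc <- 0
  lv <- vapply(frames, laplacian_variance, 0)
  ratio <- if (min(lv) <= 0) Inf else max(lv) / min(lv)
  scores <- c(defect_fraction = defect, continuity_ncc = ncc, blur_ratio = ratio)
  pass <- defect <= thresholds$defect_fraction_max &&
    ncc >= thresholds$continuity_ncc_min &&
    ratio <= thresholds$blur_ratio_max
  list(pass = pass, scores = scores)
}

#' Histogram specification toward the middle frame
#'
#' Remaps the intensities of frames 0 and 2 by the monotone 8-bit transform
#' that matches their empirical CDFs to the middle frame's; the middle
#' frame is returned unchanged.  A constant reference makes the operation a
#' no-op with a warning flag.
#'
#' @param frames list of three same-shaped matrices in `[0, 1]`.
#' @return list of three matrices; attribute `"constant_reference"` is set
#'   to `TRUE` when the reference had no dynamic range.
#' @export
histogram_specification <- function(frames) {
  ref <- round(frames[[2L]] * 255)
  if (stats::sd(ref) == 0) {
    out <- frames
    attr(out, "constant_reference") <- TRUE
    return(out)
  }
  cdf_ref <- cumsum(tabulate(as.vector(ref) + 1L, 256L)) / length(ref)
  remap <- function(img) {
    g <- round(img * 255)
    cdf_src <- cumsum(tabulate(as.vector(g) + 1L, 256L)) / length(g)
    # nearest reference level by CDF value; monotone since both CDFs are
    # non-decreasing (ties resolve to the lower level)
    lo <- findInterval(cdf_src, cdf_ref, left.open = TRUE)
    hi <- pmin(lo + 1L, 256L)
    lo <- pmax(lo, 1L)
    pick_hi <- abs(cdf_ref[hi] - cdf_src) < abs(cdf_ref[lo] - cdf_src)
    lut <- ifelse(pick_hi, hi, lo) - 1L
    lut <- pmin(pmax(lut, 0L), 255L)
    matrix(lut[g + 1L] / 255, nrow(img), ncol(img))
  }
  list(remap(frames[[1L]]), frames[[2L]], remap(frames[[3L]]))
}

#' Random augmentation of a triplet sample
#'
#' Independent random horizontal flip, vertical flip and temporal-order
#' swap (frames 0 and 2 exchanged, the middle frame fixed), plus a random
#' crop to `crop` when the frames are larger.  Fully determined by `seed`.
#'
#' @param frames list of three same-shaped matrices.
#' @param seed integer seed.
#' @param crop target crop size (applied only if frames are larger).
#' @return list with `frames` and `decisions`.
#' @export
augment_sample <- function(frames, seed, crop = NULL) {
  with_seed(seed, {
    hflip <- stats::runif(1) < 0.5
    vflip <- stats::runif(1) < 0.5
    tswap <- stats::runif(1) < 0.5
    H <- nrow(frames[[1L]]); W <- ncol(frames[[1L]])
    if (!is.null(crop) && (H > crop || W > crop)) {
      r0 <- sample.int(H - crop + 1L, 1L) - 1L
      c0 <- sample.int(W - crop + 1L, 1L) - 1L
      frames <- lapply(frames, function(f) f[r0 + seq_len(crop), c0 + seq_len(crop)])
    } else { r0 <- 0L; c0 <- 0L }
    tf <- function(f) {
      if (vflip) f <- f[rev(seq_len(nrow(f))), , drop = FALSE]
      if (hflip) f <- f[, rev(seq_len(ncol(f))), drop = FALSE]
      f
    }
    frames <- lapply(frames, tf)
    if (tswap) frames <- frames[c(3L, 2L, 1L)]
    list(frames = frames,
         decisions = list(hflip = hflip, vflip = vflip, temporal_swap = tswap,
                          crop_origin = c(r0, c0)))
  })
}

#' Load a slice volume from a directory of images
#'
#' Reads all PNG/TIFF files of a directory in lexical order as one ordered
#' stack of grayscale slices.
#'
#' @param source directory path, or a list of `H x W` matrices.
#' @return object of class `"slice_volume"`: list with `slices` and
#'   `source`.
#' @export
slice_volume <- function(source) {
  if (is.character(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop(sprintf("no PNG/TIFF slices found in %s", source))
    slices <- lapply(files, read_slice)
    src <- source
  } else {
    slices <- source
    src <- "<in-memory>"
  }
  shp <- dim(slices[[1L]])
  for (s in slices) if (!identical(dim(s), shp))
    stop("all slices of a volume must share one shape")
  structure(list(slices = slices, source = src), class = "slice_volume")
}

#' Build a triplet dataset from a slice volume
#'
#' For every consecutive slice triple: align by template matching, crop on
#' the stride grid, quality-filter each crop, histogram-match the outer
#' frames to the middle one, and write passing samples as PNG triplets with
#' a JSON manifest.  The train/validation/test split (3:1:1) is assigned by
#' contiguous middle-slice-index blocks so that no slice contributes crops
#' to more than one split.
#'
#' @param volume a [slice_volume()].
#' @param out_dir output directory.
#' @param crop,stride crop geometry (see [crop_grid()]).
#' @param search_radius alignment search radius, pixels.
#' @param thresholds a [quality_thresholds()].
#' @param hist_spec apply histogram specification (default `TRUE`).
#' @return the manifest, invisibly; failures are recorded with reasons.
#' @export
build_dataset <- function(volume, out_dir, crop = 512L, stride = 512L,
                          search_radius = 10L,
                          thresholds = quality_thresholds(),
                          hist_spec = TRUE) {
  stopifnot(inherits(volume, "slice_volume"))
  n <- length(volume$slices)
  if (n < 3L) stop("a volume needs at least 3 slices for triplet extraction")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mids <- 2:(n - 1L)
  n_val <- length(mids) %/% 5L
  n_test <- length(mids) %/% 5L
  split_of <- rep(c("train", "val", "test"),
                  c(length(mids) - n_val - n_test, n_val, n_test))
  samples <- list(); failures <- list()
  si <- 0L
  for (mi in seq_along(mids)) {
    m <- mids[mi]
    al <- align_triplet(volume$slices[(m - 1L):(m + 1L)], search_radius)
    if (al$failed) {
      failures <- c(failures, list(list(slice = m, reason = "alignment_ncc_below_floor")))
      next
    }
    for (cr in crop_grid(al$frames, crop, stride)) {
      qc <- quality_filter(cr$frames, thresholds)
      if (!qc$pass) {
        failures <- c(failures, list(list(
          slice = m, origin = unname(cr$origin), reason = "quality_filter",
          scores = as.list(qc$scores))))
        next
      }
      fr <- if (hist_spec) histogram_specification(cr$frames) else cr$frames
      si <- si + 1L
      id <- sprintf("slice%03d_r%05d_c%05d", m, cr$origin[1L], cr$origin[2L])
      files <- sprintf("%s_f%d.png", id, 0:2)
      for (k in 1:3) write_slice(fr[[k]], file.path(out_dir, files[k]))
      samples <- c(samples, list(list(
        id = id, slice = m, origin = unname(cr$origin),
        split = split_of[mi], files = files, qc = as.list(qc$scores))))
    }
  }
  manifest <- list(kind = "ssan_triplet_manifest", version = 1L,
                   n = length(samples), source = volume$source,
                   crop = crop, stride = stride,
                   thresholds = unclass(thresholds),
                   samples = samples, failures = failures)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
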