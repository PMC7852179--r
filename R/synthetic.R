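# Synthetic serial-EM triplet generator.
#
# Emulates the statistical structure interpolation training exploits in real
# serial-section EM: a shared underlying tissue texture, a smooth random
# deformation between consecutive sections, a global stage drift, and
# per-section style differences (noise level, blur, contrast).  Frames 0
# and 2 are warps of the base texture by -(u + drift) and +(u + drift), so
# the un-deformed base is the exact temporal middle by construction.

#' Synthetic triplet configuration
#'
#' @param size `c(H, W)` in pixels (at least 16 in each dimension).
#' @param texture `"membrane"` (thin dark ridges between cell-like regions
#'   plus elliptical dark blobs), `"blob"` or `"filtered_noise"`.
#' @param deform_magnitude maximum displacement magnitude between
#'   consecutive slices, pixels.
#' @param deform_smoothness correlation length of the displacement field,
#'   pixels.
#' @param drift global translation per slice step, pixels (length 2
#'   `c(dy, dx)` or a scalar applied to both axes).
#' @param noise_sigma per-frame additive Gaussian noise sd, `[0, 1]` gray
#'   units, length 3.
#' @param blur_sigma per-frame Gaussian blur sd in pixels, length 3.
#' @param contrast_jitter half-width of the per-frame multiplicative
#'   contrast range (factor drawn in `1 +/- contrast_jitter`).
#' @param blob_density expected dark-blob count per 4096 pixels of the
#'   membrane/blob textures.
#' @param region_density expected membrane-region (cell) count per 4096
#'   pixels.
#' @param seed integer seed; the generator is bit-deterministic given the
#'   configuration and seed.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(size = c(64L, 64L), texture = c("membrane", "blob", "filtered_noise"),
                             deform_magnitude = 3, deform_smoothness = 12,
                             drift = 1, noise_sigma = c(0.02, 0.01, 0.03),
                             blur_sigma = c(0.5, 0, 1.0), contrast_jitter = 0.05,
                             blob_density = 6, region_density = 14, seed = 1L) {
  texture <- match.arg(texture)
  stopifnot(length(size) == 2L, deform_magnitude >= 0, deform_smoothness > 0,
            length(noise_sigma) == 3L, length(blur_sigma) == 3L,
            contrast_jitter >= 0, blob_density >= 0)
  if (any(size < 16L)) stop("degenerate size: images must be at least 16 px")
  if (length(drift) == 1L) drift <- c(drift, drift)
  structure(list(size = as.integer(size), texture = texture,
                 deform_magnitude = deform_magnitude,
                 deform_smoothness = deform_smoothness, drift = drift,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 contrast_jitter = contrast_jitter, blob_density = blob_density,
                 region_density = region_density, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Nearest and second-nearest seed-point distances for every pixel,
# O(N * n_seeds) memory-light sweep.
.voronoi_d12 <- function(H, W, sy, sx) {
  py <- rep(seq_len(H), times = W)
  px <- rep(seq_len(W), each = H)
  d1 <- rep(Inf, H * W); d2 <- d1
  for (s in seq_along(sy)) {
    d <- sqrt((py - sy[s])^2 + (px - sx[s])^2)
    closer <- d < d1
    d2 <- ifelse(closer, d1, pmin(d2, d))
    d1 <- pmin(d1, d)
  }
  list(d1 = matrix(d1, H, W), d2 = matrix(d2, H, W))
}

.add_blobs <- function(img, n_blobs) {
  H <- nrow(img); W <- ncol(img)
  py <- rep(seq_len(H), times = W)
  px <- rep(seq_len(W), each = H)
  for (b in seq_len(n_blobs)) {
    cy <- stats::runif(1, 3, H - 2); cx <- stats::runif(1, 3, W - 2)
    ra <- stats::runif(1, 1.5, 4); rb <- stats::runif(1, 1.5, 4)
    th <- stats::runif(1, 0, pi)
    dy <- py - cy; dx <- px - cx
    a <- cos(th) * dy + sin(th) * dx
    c2 <- -sin(th) * dy + cos(th) * dx
    q <- (a / ra)^2 + (c2 / rb)^2
    img <- img - matrix(0.4 * exp(-q^2), H, W)
  }
  img
}

#' Generate the shared base texture
#'
#' `"membrane"` draws random seed points, places thin dark ridges along the
#' region boundaries (where the nearest and second-nearest seed distances
#' coincide, the boundary set of the seed-point tessellation) on a bright
#' background, and adds elliptical dark blobs emulating mitochondria plus a
#' low-frequency intensity field.  Values are clamped to `[0, 1]`.
#'
#' @param cfg a [synthetic_config()].
#' @return `H x W` matrix with attributes `n_blobs` and `n_regions`.
#' @export
generate_base_texture <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  H <- cfg$size[1L]; W <- cfg$size[2L]
  with_seed(cfg$seed, {
    img <- switch(cfg$texture,
      membrane = {
        n_regions <- max(4L, stats::rpois(1L, cfg$region_density * H * W / 4096))
        sy <- stats::runif(n_regions, 1, H)
        sx <- stats::runif(n_regions, 1, W)
        d <- .voronoi_d12(H, W, sy, sx)
        ridge <- exp(-((d$d2 - d$d1)^2) / (2 * 1.8^2))
        base <- 0.78 - 0.55 * ridge
        n_blobs <- stats::rpois(1L, cfg$blob_density * H * W / 4096)
        base <- .add_blobs(base, n_blobs)
        lowf <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), 8)
        lowf <- 0.10 * lowf / max(1e-8, stats::sd(lowf))
        # band-limited texture grain: white noise would alias under the
        # sub-pixel warps that relate consecutive slices
        grain <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), 1.0)
        grain <- 0.03 * grain / max(1e-8, stats::sd(grain))
        out <- base + lowf + grain
        attr(out, "n_blobs") <- n_blobs
        attr(out, "n_regions") <- n_regions
        out
      },
      blob = {
        n_blobs <- stats::rpois(1L, cfg$blob_density * H * W / 4096)
        out <- .add_blobs(matrix(0.75, H, W), n_blobs) +
          matrix(stats::rnorm(H * W, sd = 0.04), H, W)
        attr(out, "n_blobs") <- n_blobs
        out
      },
      filtered_noise = {
        f <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), 3)
        q <- stats::quantile(f, c(0.02, 0.98))
        0.1 + 0.8 * (f - q[1L]) / max(1e-8, q[2L] - q[1L])
      })
    at <- attributes(img)
    img <- clamp01(img)
    attributes(img) <- at
    img
  })
}

# Smooth random displacement field scaled to the requested peak magnitude.
.displacement_field <- function(H, W, magnitude, smoothness) {
  if (magnitude == 0) return(list(uy = matrix(0, H, W), ux = matrix(0, H, W)))
  uy <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), smoothness)
  ux <- gaussian_blur(matrix(stats::rnorm(H * W), H, W), smoothness)
  m <- max(sqrt(uy^2 + ux^2))
  list(uy = uy * magnitude / m, ux = ux * magnitude / m)
}

#' Bilinear warp with reflected boundaries
#'
#' Pull-back sampling: `out(p) = img(p + d(p))` where `d = (dy, dx)` may be
#' constant or per-pixel fields.
#'
#' @param img `H x W` matrix.
#' @param dy,dx displacement fields (matrices) or scalars, pixels.
#' @return warped `H x W` matrix.
#' @export
warp_bilinear <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  py <- rep(seq_len(H), times = W) + as.vector(if (is.matrix(dy)) dy else matrix(dy, H, W))
  px <- rep(seq_len(W), each = H) + as.vector(if (is.matrix(dx)) dx else matrix(dx, H, W))
  refl <- function(x, n) {
    # reflect into [1, n]
    x <- abs(x - 1) %% (2 * (n - 1))
    1 + ifelse(x > (n - 1), 2 * (n - 1) - x, x)
  }
  py <- refl(py, H); px <- refl(px, W)
  y0 <- pmin(floor(py), H - 1L); x0 <- pmin(floor(px), W - 1L)
  fy <- py - y0; fx <- px - x0
  i00 <- y0 + (x0 - 1) * H
  v <- (1 - fy) * (1 - fx) * img[i00] + fy * (1 - fx) * img[i00 + 1] +
    (1 - fy) * fx * img[i00 + H] + fy * fx * img[i00 + H + 1]
  matrix(v, H, W)
}

.apply_style <- function(img, blur, noise, cfac) {
  out <- gaussian_blur(img, blur)
  out <- 0.5 + cfac * (out - 0.5)
  if (noise > 0) out <- out + matrix(stats::rnorm(length(out), sd = noise),
                                     nrow(out), ncol(out))
  clamp01(out)
}

#' Generate one synthetic triplet
#'
#' Samples a smooth displacement field `u`, warps the base texture by
#' `-(u + drift)` and `+(u + drift)` for frames 0 and 2, and applies the
#' per-frame style (blur, additive noise, contrast jitter).  Frame 1 is the
#' styled but un-deformed base: the exact temporal middle.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `"synthetic_triplet"`: `frames` (list of three
#'   `H x W` matrices), `displacement` (list `uy`, `ux`: the per-slice-step
#'   field), `drift`, and `config`.
#' @export
generate_triplet <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  H <- cfg$size[1L]; W <- cfg$size[2L]
  if (cfg$deform_magnitude > H / 4 || cfg$deform_magnitude > W / 4)
    stop("deform_magnitude exceeds a quarter of the frame: tissue continuity violated")
  base <- generate_base_texture(cfg)
  attributes(base) <- list(dim = dim(base))
  with_seed(cfg$seed + 1000003L, {
    u <- .displacement_field(H, W, cfg$deform_magnitude, cfg$deform_smoothness)
    cf <- 1 + stats::runif(3L, -cfg$contrast_jitter, cfg$contrast_jitter)
    f0 <- .apply_style(warp_bilinear(base, -(u$uy + cfg$drift[1L]), -(u$ux + cfg$drift[2L])),
                       cfg$blur_sigma[1L], cfg$noise_sigma[1L], cf[1L])
    f1 <- .apply_style(base, cfg$blur_sigma[2L], cfg$noise_sigma[2L], cf[2L])
    f2 <- .apply_style(warp_bilinear(base, u$uy + cfg$drift[1L], u$ux + cfg$drift[2L]),
                       cfg$blur_sigma[3L], cfg$noise_sigma[3L], cf[3L])
    structure(list(frames = list(f0, f1, f2),
                   displacement = u, drift = cfg$drift, config = cfg),
              class = "synthetic_triplet")
  })
}

#' Generate and write a synthetic triplet dataset
#'
#' Writes `n` triplets as three 8-bit grayscale PNGs each plus a JSON
#' manifest with per-sample seeds and a contiguous 3:1:1
#' train/validation/test split.
#'
#' @param n number of triplets (`n = 0` writes an empty manifest).
#' @param cfg a [synthetic_config()]; sample `i` uses seed `cfg$seed + i`.
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly; also written to
#'   `file.path(out_dir, "manifest.json")`.
#' @export
generate_dataset <- function(n, cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"), n >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_val <- n %/% 5L
  n_test <- n %/% 5L
  split <- rep(c("train", "val", "test"), c(n - n_val - n_test, n_val, n_test))
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cfg
    ci$seed <- cfg$seed + i
    tri <- generate_triplet(ci)
    files <- sprintf("sample_%04d_f%d.png", i, 0:2)
    for (k in 1:3) write_slice(tri$frames[[k]], file.path(out_dir, files[k]))
    samples[[i]] <- list(id = sprintf("sample_%04d", i), seed = ci$seed,
                         split = split[i], files = files)
  }
  manifest <- list(kind = "ssan_triplet_manifest", version = 1L, n = n,
                   config_hash = config_hash(cfg),
                   config = unclass(cfg), samples = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_hash <- function(cfg) {
  raw <- serialize(lapply(unclass(cfg), unname), NULL, version = 2L)
  sprintf("%08x", sum(as.integer(raw) * (seq_along(raw) %% 251)) %% 4294967291)
}
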