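# Small shared helpers.

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  expr
}

check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", name))
  if (!all(is.finite(img))) stop(sprintf("non-finite values in %s", name))
  invisible(TRUE)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Read a grayscale slice image
#'
#' Reads an 8- or 16-bit PNG (or TIFF, if the tiff package is installed)
#' as an `H x W` matrix in `[0, 1]`.  Color images are converted to
#' luminance by channel averaging.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_slice <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF slices requires the 'tiff' package")
    tiff::readTIFF(path)
  } else stop(sprintf("unsupported slice format '%s' (PNG or TIFF expected): %s", ext, path))
  if (length(dim(img)) == 3L) img <- rowMeans(img, dims = 2L)
  img
}

#' Write a grayscale slice as 8-bit PNG
#'
#' Values are clamped to `[0, 1]` and quantized to 8 bits.
#'
#' @param img numeric `H x W` matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_slice <- function(img, path) {
  check_image(img)
  png::writePNG(quantize8(img), path)
  invisible(path)
}

# Quantize to the 8-bit grid (round-trip exact through writePNG/readPNG).
quantize8 <- function(img) round(clamp01(img) * 255) / 255

# Gaussian blur via separable convolution with reflected edges.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  kx <- exp(-((-r:r)^2) / (2 * sigma^2))
  kx <- kx / sum(kx)
  sep_filter(img, kx)
}

# Separable symmetric filter with reflect padding.
sep_filter <- function(img, k) {
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  ridx <- reflect_idx(H, r)
  cidx <- reflect_idx(W, r)
  padded <- img[ridx, , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * padded[(i - 1L) + seq_len(H), , drop = FALSE]
  padded <- out[, cidx, drop = FALSE]
  out2 <- matrix(0, H, W)
  for (i in seq_along(k)) out2 <- out2 + k[i] * padded[, (i - 1L) + seq_len(W), drop = FALSE]
  out2
}

reflect_idx <- function(n, r) {
  idx <- c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
  pmin(pmax(idx, 1L), n)
}

# Variance of the 4-neighbour Laplacian response; a standard sharpness score.
laplacian_variance <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) return(0)
  c0 <- img[2:(H - 1), 2:(W - 1)]
  lap <- img[1:(H - 2), 2:(W - 1)] + img[3:H, 2:(W - 1)] +
    img[2:(H - 1), 1:(W - 2)] + img[2:(H - 1), 3:W] - 4 * c0
  stats::var(as.vector(lap))
}
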