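# Interpolation quality metrics: PSNR, SSIM and interpolation error (IE).

#' PSNR, SSIM and interpolation error for one frame pair
#'
#' PSNR is `-10 log10(MSE)` in dB on the `[0, 1]` scale (`Inf`, flagged,
#' for identical images).  SSIM uses the standard 11x11 Gaussian window
#' (`sigma = 1.5`) with `K1 = 0.01`, `K2 = 0.03` and dynamic range 1.
#' IE is the root-mean-square pixel difference expressed in 8-bit gray
#' levels (`255 * RMSE`), the interpolation-error convention of the
#' frame-synthesis literature.
#'
#' @param pred,gt same-shaped images in `[0, 1]`.
#' @return named list with `psnr`, `ssim`, `ie` and `exact` (TRUE when the
#'   images are identical and PSNR is infinite).
#' @export
compute_metrics <- function(pred, gt) {
  check_same_shape(pred, gt)
  if (any(pred < -1e-9) || any(pred > 1 + 1e-9) || any(gt < -1e-9) || any(gt > 1 + 1e-9))
    stop("metric inputs must lie in [0, 1]")
  mse <- mean((pred - gt)^2)
  list(psnr = if (mse == 0) Inf else -10 * log10(mse),
       ssim = ssim_index(pred, gt),
       ie = 255 * sqrt(mse),
       exact = mse == 0)
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian weighting window (`sigma = 1.5`),
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 1`; window means are
#' computed with reflected borders.
#'
#' @param x,y same-shaped images in `[0, 1]`.
#' @return scalar in `[-1, 1]`.
#' @export
ssim_index <- function(x, y, K1 = 0.01, K2 = 0.03, L = 1) {
  check_same_shape(x, y)
  k <- exp(-((-5:5)^2) / (2 * 1.5^2)); k <- k / sum(k)
  mu_x <- sep_filter(x, k); mu_y <- sep_filter(y, k)
  sxx <- sep_filter(x * x, k) - mu_x^2
  syy <- sep_filter(y * y, k) - mu_y^2
  sxy <- sep_filter(x * y, k) - mu_x * mu_y
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * sxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (sxx + syy + c2))
  mean(s)
}
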