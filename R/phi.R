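# Frozen feature networks for the perceptual loss terms.
#
# The loss definitions are agnostic to the extractor: any deterministic,
# frozen map from an image to a list of C_j x H_j x W_j activations works.
# Two self-contained variants ship with the package: `identity` (the image
# itself as a single one-channel layer) and `convstack` (a fixed-seed stack
# of random 3x3 convolutions with ReLU and 2x2 average pooling, giving four
# multi-scale layers in the spirit of the usual four-tap perceptual-loss
# convention).  A pretrained extractor can be supplied as a user function
# returning the same structure.

#' Construct a frozen feature network
#'
#' @param variant `"convstack"` (default; four fixed random conv stages with
#'   ReLU and 2x2 average pooling between stages) or `"identity"` (a single
#'   layer equal to the input image).
#' @param seed seed for the fixed random weights of the convstack.
#' @param channels channel counts of the four convstack stages.
#' @return object of class `"feature_network"`.
#' @export
feature_network <- function(variant = c("convstack", "identity"), seed = 7L,
                            channels = c(4L, 8L, 12L, 16L)) {
  variant <- match.arg(variant)
  layers <- NULL
  if (variant == "convstack") {
    stopifnot(length(channels) == 4L)
    cin <- c(1L, channels[-4L])
    layers <- with_seed(seed, lapply(seq_len(4L), function(j) {
      # a fifth of the He scale: keeps the four-layer activation (and
      # hence Gram) magnitudes in the regime the published loss weighting
      # presumes for its pretrained extractor, so alpha1 = 1e6 makes the
      # style term a regularizer of comparable size to the pixel term
      # rather than swamping it
      sd <- 0.2 * sqrt(2 / (9 * cin[j]))
      list(w = matrix(stats::rnorm(9L * cin[j] * channels[j], sd = sd),
                      9L * cin[j], channels[j]),
           b = rep(0, channels[j]))
    }))
  }
  structure(list(variant = variant, layers = layers, channels = channels),
            class = "feature_network")
}

# Apply phi on a tape; x is a (B*N) x 1 node of B stacked H x W images.
# Returns a list of layers: list(node, H, W, C) with per-sample row blocks.
phi_apply_tape <- function(phi, tp, x, H, W, B = 1L) {
  if (phi$variant == "identity")
    return(list(list(node = x, H = H, W = W, C = 1L)))
  out <- vector("list", 4L)
  cur <- x; ch <- H; cw <- W
  for (j in 1:4) {
    w <- tp_const(tp, phi$layers[[j]]$w)
    b <- tp_const(tp, matrix(phi$layers[[j]]$b, nrow = 1L))
    cur <- tp_relu(tp, tp_conv3(tp, cur, w, b, ch, cw, B))
    out[[j]] <- list(node = cur, H = ch, W = cw, C = ncol(cur$v))
    if (j < 4L && ch >= 2L && cw >= 2L) {
      cur <- tp_avgpool2(tp, cur, ch, cw, B)
      ch <- ch %/% 2L; cw <- cw %/% 2L
    }
  }
  out
}

# Plain (value-only) application; img is an H x W matrix in [0, 1].
phi_apply <- function(phi, img) {
  check_image(img)
  tp <- tape_new(grad = FALSE)
  x <- tp_const(tp, matrix(as.vector(img), ncol = 1L))
  lapply(phi_apply_tape(phi, tp, x, nrow(img), ncol(img)), function(l) {
    list(values = l$node$v, H = l$H, W = l$W, C = l$C)
  })
}
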