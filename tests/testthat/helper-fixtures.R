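# Shared fixtures: small random feature maps and triplets, built in code.

rand_map <- function(C, H, W, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(C * H * W), C, H * W)
}

tiny_cfg_8 <- function() attention_config(k = 2L, level1 = c(2L, 2L, 4L, 4L),
                                          level2 = c(2L, 2L, 2L, 2L))

tiny_triplets <- function(n, seed0 = 100L, size = 64L, split = NULL) {
  lapply(seq_len(n), function(i) {
    cfg <- synthetic_config(size = c(size, size), seed = seed0 + i)
    sp <- if (is.null(split)) "train" else split[[i]]
    list(frames = generate_triplet(cfg)$frames, split = sp)
  })
}

# split vector for n samples in 3:1:1 contiguous blocks
split_311 <- function(n) {
  nv <- n %/% 5L; nt <- n %/% 5L
  rep(c("train", "val", "test"), c(n - nv - nt, nv, nt))
}
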