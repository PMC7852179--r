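Package: ssan
Title: Sparse Self-Attention Aggregation Networks for Serial-Section EM
    Slice Interpolation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Interpolates a missing middle slice from its two neighbouring
    serial electron-microscopy sections with a sparse self-attention
    aggregation network. Provides the multi-level interlaced sparse
    attention-aware layer with block-diagonal affinity factorization and
    operation-count accounting, a siamese residual dense feature extractor
    with sigmoid-mask warp fusion, Gram-matrix style losses including an
    adaptive style-balance loss and a Charbonnier pixel term, a synthetic
    EM-triplet generator with ground-truth deformation fields, a triplet
    dataset-construction pipeline (template-matching alignment, grid
    cropping, quality filtering, histogram specification), and a seeded
    CPU training and evaluation harness reporting PSNR, SSIM and
    interpolation error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
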