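# YAML configuration surface used by the command-line wrapper: one file
# with model:, loss:, train: and data: blocks mapped onto the package's
# configuration constructors.

#' Read a YAML run configuration
#'
#' Recognized blocks (all optional, defaults apply):
#' \preformatted{
#' model:
#'   preset: tiny            # or default
#'   channels: 16            # backbone output channels C
#'   blocks: 2               # residual dense blocks D
#'   convs_per_block: 2
#'   growth: 8
#'   base_channels: 8        # G0
#'   k: 2
#'   level1: [4, 4, 16, 16]
#'   level2: [4, 4, 4, 4]
#'   gate_init: 0
#' loss:
#'   alpha: [1e6, 1, 1]
#'   beta: [0.1, 1, 0.1]
#'   eps: 1e-6
#'   phi: convstack          # or identity
#' train:
#'   preset: desk            # or paper
#'   epochs: [10]
#'   lr: 1e-3
#'   lr_factor: 0.1
#'   batch_size: 3
#'   seed: 1
#'   augment: true
#' data:
#'   dir: path/to/dataset
#' }
#'
#' @param path YAML file path.
#' @return list with `model` ([ssan_config()]), `loss` ([loss_weights()]),
#'   `train` ([train_config()]), `phi` ([feature_network()]) and `data`.
#' @export
ssan_read_config <- function(path) {
  y <- yaml::read_yaml(path)
  m <- y$model %||% list()
  preset <- m$preset %||% "tiny"
  base <- ssan_config(preset = preset)
  srdn <- srdn_config(G0 = m$base_channels %||% base$srdn$G0,
                      D = m$blocks %||% base$srdn$D,
                      convs_per_block = m$convs_per_block %||% base$srdn$convs_per_block,
                      growth = m$growth %||% base$srdn$growth,
                      C = m$channels %||% base$srdn$C)
  att <- attention_config(k = m$k %||% base$attention$k,
                          level1 = unlist(m$level1 %||% base$attention$level1),
                          level2 = unlist(m$level2 %||% base$attention$level2),
                          levels = m$levels %||% base$attention$levels,
                          gate_init = m$gate_init %||% base$attention$gate_init)
  model <- ssan_config(srdn = srdn, attention = att,
                       fusion_width = m$fusion_width %||% base$fusion_width,
                       preset = preset)
  l <- y$loss %||% list()
  alpha <- as.numeric(unlist(l$alpha %||% c(1e6, 1, 1)))
  loss <- loss_weights(alpha1 = alpha[1L], alpha2 = alpha[2L], alpha3 = alpha[3L],
                       beta = as.numeric(unlist(l$beta %||% c(0.1, 1, 0.1))),
                       eps = as.numeric(l$eps %||% 1e-6))
  phi <- feature_network(variant = l$phi %||% "convstack")
  tr <- y$train %||% list()
  tpreset <- tr$preset %||% "desk"
  tbase <- train_config(preset = tpreset)
  train <- train_config(epochs = unlist(tr$epochs %||% tbase$epochs),
                        lr = as.numeric(tr$lr %||% tbase$lr),
                        lr_factor = tr$lr_factor %||% tbase$lr_factor,
                        batch_size = tr$batch_size %||% tbase$batch_size,
                        seed = tr$seed %||% tbase$seed,
                        augment = tr$augment %||% tbase$augment,
                        preset = tpreset)
  list(model = model, loss = loss, train = train, phi = phi, data = y$data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
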