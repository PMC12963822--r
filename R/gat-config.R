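#' Architecture configuration for the graph attention model
#'
#' Fixes the three-layer graph attention architecture: layer 1 maps the
#' 2-dimensional input (standardized expression and m5C level) through two
#' 16-dimensional attention heads; layer 2 consumes the concatenated
#' 32-dimensional representation with two further 16-dimensional heads;
#' layer 3 compresses the resulting 32 dimensions to a single importance
#' logit with one head. A 32-dimensional edge-type embedding feeds every
#' layer's attention logits, batch normalization follows layers 1 and 2,
#' activations are ELU, and dropout (rate 0.3) is applied to node
#' representations after each activation.
#'
#' @param in_dim Input feature dimension (2: expression and m5C channels).
#' @param heads Attention heads per layer.
#' @param dim_per_head Output dimension of each head, per layer.
#' @param edge_embed_dim Dimension of the per-layer edge-type embedding.
#' @param dropout Dropout rate on node representations, in `[0, 1)`.
#' @param attn_dropout Dropout rate on attention coefficients (0 disables;
#'   off by default).
#' @param leaky_slope Negative slope of the LeakyReLU inside the attention
#'   logit (0.2, the usual graph-attention convention).
#' @param bn_eps,bn_momentum Batch-normalization stabilizer and
#'   running-statistics momentum.
#' @return A validated `gat_config` list.
#' @export
gat_config <- function(in_dim = 2L, heads = c(2L, 2L, 1L),
                       dim_per_head = c(16L, 16L, 1L), edge_embed_dim = 32L,
                       dropout = 0.3, attn_dropout = 0, leaky_slope = 0.2,
                       bn_eps = 1e-5, bn_momentum = 0.1) {
  stopifnot(length(heads) == 3L, length(dim_per_head) == 3L)
  if (dropout < 0 || dropout >= 1) abort("`dropout` must lie in [0, 1).")
  if (attn_dropout < 0 || attn_dropout >= 1) abort("`attn_dropout` must lie in [0, 1).")
  cfg <- list(in_dim = as.integer(in_dim), heads = as.integer(heads),
              dim_per_head = as.integer(dim_per_head),
              edge_embed_dim = as.integer(edge_embed_dim),
              dropout = dropout, attn_dropout = attn_dropout,
              leaky_slope = leaky_slope, bn_eps = bn_eps, bn_momentum = bn_momentum)
  cfg$layer_in <- c(cfg$in_dim,
                    cfg$heads[1] * cfg$dim_per_head[1],
                    cfg$heads[2] * cfg$dim_per_head[2])
  structure(cfg, class = "gat_config")
}

#' Optimization configuration for model training
#'
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param weight_decay L2 coefficient added to the gradient of every
#'   trainable parameter (default 1e-4).
#' @param max_epochs Upper bound on training epochs (default 200).
#' @param patience Early stopping: training ends once the validation loss
#'   has failed to improve for this many consecutive epochs (default 30).
#' @param val_fraction Validation share of the stratified split (0.2).
#' @param seed Integer seed governing the split, parameter initialization
#'   and dropout.
#' @param beta1,beta2,adam_eps Adam moment coefficients and stabilizer.
#' @return A validated `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 1e-4,
                         max_epochs = 200L, patience = 30L, val_fraction = 0.2,
                         seed = 1L, beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  max_epochs <- assert_count(max_epochs, "max_epochs")
  patience <- assert_count(patience, "patience")
  if (patience >= max_epochs) abort("`patience` must be smaller than `max_epochs`.")
  val_fraction <- assert_fraction(val_fraction, "val_fraction")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 max_epochs = max_epochs, patience = patience,
                 val_fraction = val_fraction, seed = seed,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}
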