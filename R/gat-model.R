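# Edge arrays consumed by the attention layers: the stored directed edges
# plus one structural self-loop per node carrying a reserved edge type
# (index = |vocab| + 1), so every node has a defined neighborhood.
edge_arrays <- function(net) {
  n <- length(net$nodes)
  self_type <- length(net$edge_type_vocab) + 1L
  src <- c(net$edges$from, seq_len(n))
  dst <- c(net$edges$to, seq_len(n))
  type <- c(net$edges$type, rep(self_type, n))
  ne <- length(src)
  # sparse segment-sum operators (edges -> nodes / edge types), built once
  # per network and reused across every layer, head and epoch
  list(src = src, dst = dst, type = type, n = n, n_types = self_type,
       agg_dst = Matrix::sparseMatrix(i = dst, j = seq_len(ne), x = 1,
                                      dims = c(n, ne)),
       agg_src = Matrix::sparseMatrix(i = src, j = seq_len(ne), x = 1,
                                      dims = c(n, ne)),
       agg_type = Matrix::sparseMatrix(i = type, j = seq_len(ne), x = 1,
                                       dims = c(self_type, ne)))
}

seg_sum_vec <- function(agg, v) (agg %*% v)@x
seg_sum_mat <- function(agg, m) {
  r <- agg %*% m
  matrix(r@x, nrow(r), ncol(r))
}
add_cols <- function(x, b) x + rep(b, each = nrow(x))
mul_cols <- function(x, b) x * rep(b, each = nrow(x))

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Node-feature transforms use Glorot-uniform initialization, attention
#' vectors Glorot-uniform with fan-out 1, biases zero, edge-type embedding
#' tables and projections small-uniform in \[-0.1, 0.1\]. One extra edge
#' type beyond the network vocabulary is reserved for structural
#' self-loops. A fixed seed yields byte-identical parameters.
#'
#' @param config A [gat_config()].
#' @param n_edge_types Size of the network's edge-type vocabulary
#'   (`length(net$edge_type_vocab)`).
#' @param seed Integer seed.
#' @return A `gat_parameters` nested list: per layer, per head `W`,
#'   `a_src`, `a_dst`, `a_edge`, `bias`; per layer `edge_embed`,
#'   `edge_proj`; batch-norm `gamma`, `beta`, `running_mean`,
#'   `running_var` for layers 1-2.
#' @export
init_gat_parameters <- function(config, n_edge_types, seed = 1L) {
  stopifnot(inherits(config, "gat_config"))
  n_types <- as.integer(n_edge_types) + 1L  # + reserved self-loop type
  with_seed_if(seed, {
    layers <- lapply(1:3, function(l) {
      d_in <- config$layer_in[l]
      d_out <- config$dim_per_head[l]
      heads <- lapply(seq_len(config$heads[l]), function(h) {
        list(W = glorot(d_in, d_out),
             a_src = runif(d_out, -1, 1) * sqrt(6 / (d_out + 1)),
             a_dst = runif(d_out, -1, 1) * sqrt(6 / (d_out + 1)),
             a_edge = runif(1, -0.1, 0.1),
             bias = numeric(d_out))
      })
      list(heads = heads,
           edge_embed = matrix(runif(n_types * config$edge_embed_dim, -0.1, 0.1),
                               n_types, config$edge_embed_dim),
           edge_proj = runif(config$edge_embed_dim, -0.1, 0.1))
    })
    bn <- lapply(1:2, function(l) {
      d <- config$heads[l] * config$dim_per_head[l]
      list(gamma = rep(1, d), beta = numeric(d),
           running_mean = numeric(d), running_var = rep(1, d))
    })
    structure(list(layers = layers, bn = bn, n_types = n_types),
              class = "gat_parameters")
  })
}

leaky_relu <- function(x, slope) x * (slope + (1 - slope) * (x > 0))
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
sigmoid <- function(x) stats::plogis(x)

# Softmax of per-edge logits grouped by destination node. A single global
# max is subtracted for stability (constant within every group, so the
# grouped softmax is unchanged). All nodes appear as destinations thanks to
# the self-loops, so rowsum() yields one row per node in index order.
segment_softmax <- function(e, ea) {
  ex <- exp(e - max(e))
  denom <- seg_sum_vec(ea$agg_dst, ex)
  ex / denom[ea$dst]
}

# One attention head: returns output rows, attention coefficients and the
# intermediates needed for backpropagation.
head_forward <- function(x, ea, hp, c_type, slope) {
  z <- x %*% hp$W
  s_dst <- drop(z %*% hp$a_dst)
  t_src <- drop(z %*% hp$a_src)
  logit <- s_dst[ea$dst] + t_src[ea$src] + hp$a_edge * c_type[ea$type]
  e <- leaky_relu(logit, slope)
  alpha <- segment_softmax(e, ea)
  out <- seg_sum_mat(ea$agg_dst, z[ea$src, , drop = FALSE] * alpha)
  out <- add_cols(out, hp$bias)
  list(out = out, z = z, logit = logit, alpha = alpha)
}

layer_forward <- function(x, ea, lp, config, layer) {
  c_type <- drop(lp$edge_embed %*% lp$edge_proj)
  hc <- lapply(lp$heads, head_forward, x = x, ea = ea, c_type = c_type,
               slope = config$leaky_slope)
  list(out = do.call(cbind, lapply(hc, `[[`, "out")),
       heads = hc, c_type = c_type, x = x)
}

bn_forward <- function(x, bn, eps, momentum, train) {
  if (train) {
    mu <- colMeans(x)
    v <- pmax(colMeans(x^2) - mu^2, 0)  # biased variance over the node batch
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  s <- sqrt(v + eps)
  xhat <- mul_cols(add_cols(x, -mu), 1 / s)
  y <- add_cols(mul_cols(xhat, bn$gamma), bn$beta)
  list(y = y, xhat = xhat, s = s, bn = bn)
}

# Full three-layer forward pass. In train mode dropout masks are drawn from
# the current RNG and batch statistics are used (and folded into the
# running estimates); in eval mode dropout is identity and batch-norm uses
# running statistics, so the pass is a pure function of its inputs.
gat_forward_cached <- function(ea, x, params, config, train = FALSE) {
  caches <- vector("list", 3L)
  h <- x
  for (l in 1:3) {
    lc <- layer_forward(h, ea, params$layers[[l]], config, l)
    if (l < 3L) {
      bnc <- bn_forward(lc$out, params$bn[[l]], config$bn_eps, config$bn_momentum, train)
      params$bn[[l]] <- bnc$bn
      act_in <- bnc$y
      act_out <- elu(act_in)
      if (train && config$dropout > 0) {
        mask <- matrix(runif(length(act_out)) >= config$dropout,
                       nrow(act_out), ncol(act_out)) / (1 - config$dropout)
        h <- act_out * mask
      } else {
        mask <- NULL
        h <- act_out
      }
      caches[[l]] <- list(layer = lc, bn = bnc, act_in = act_in, mask = mask)
    } else {
      caches[[l]] <- list(layer = lc)
    }
  }
  logit <- drop(caches[[3]]$layer$out)
  list(score = sigmoid(logit), logit = logit, caches = caches, params = params)
}

#' Run the model forward over a network
#'
#' Evaluates the three-layer attention model and returns one importance
#' score in (0, 1) per gene. Eval mode (the default) is deterministic:
#' dropout is the identity and batch normalization uses running statistics.
#'
#' @param net A `ppi_network`.
#' @param x Node feature matrix (rows in `net$nodes` order, 2 columns), as
#'   produced by [align_features()].
#' @param params A `gat_parameters` object.
#' @param config The matching [gat_config()].
#' @param mode `"eval"` or `"train"` (train mode applies dropout and batch
#'   statistics; use a seed for reproducibility).
#' @param seed Optional seed for train-mode dropout.
#' @return A tibble with columns `gene_id`, `score`.
#' @export
gat_forward <- function(net, x, params, config, mode = c("eval", "train"),
                        seed = NULL) {
  mode <- match.arg(mode)
  check_shapes(params, config, x)
  if (anyNA(x) || any(!is.finite(x))) abort("Node features contain non-finite values.")
  ea <- edge_arrays(net)
  fw <- with_seed_if(seed, gat_forward_cached(ea, x, params, config,
                                              train = mode == "train"))
  tibble(gene_id = net$nodes, score = unname(fw$score))
}

check_shapes <- function(params, config, x = NULL) {
  stopifnot(inherits(params, "gat_parameters"), inherits(config, "gat_config"))
  for (l in 1:3) {
    lp <- params$layers[[l]]
    if (length(lp$heads) != config$heads[l]) {
      abort(sprintf("Layer %d has %d heads; config expects %d.",
                    l, length(lp$heads), config$heads[l]))
    }
    for (hp in lp$heads) {
      if (!all(dim(hp$W) == c(config$layer_in[l], config$dim_per_head[l]))) {
        abort(sprintf("Layer %d weight shape %s does not match config (%d x %d).",
                      l, paste(dim(hp$W), collapse = "x"),
                      config$layer_in[l], config$dim_per_head[l]))
      }
    }
    if (ncol(lp$edge_embed) != config$edge_embed_dim) {
      abort(sprintf("Layer %d edge embedding is %d-dimensional; config expects %d.",
                    l, ncol(lp$edge_embed), config$edge_embed_dim))
    }
  }
  if (!is.null(x) && ncol(x) != config$in_dim) {
    abort(sprintf("Feature matrix has %d columns; config expects %d.",
                  ncol(x), config$in_dim))
  }
  invisible(params)
}

#' Attention coefficients of one layer and head
#'
#' Computes the normalized attention weights \eqn{\alpha_{ij}} a given
#' layer/head assigns to each directed edge (structural self-loops
#' included), from that layer's input features: the logit is
#' `LeakyReLU(a_dst . W h_i + a_src . W h_j + a_edge * (edge_proj . g(type)))`
#' followed by a softmax over each node's in-neighborhood. For every node
#' the coefficients sum to 1.
#'
#' @param net A `ppi_network`.
#' @param x The layer's input feature matrix (rows in node order, column
#'   count matching the layer's input dimension).
#' @param params,config Model parameters and configuration.
#' @param layer,head Which layer (1-3) and head to inspect.
#' @return A tibble with columns `source`, `target`, `edge_type`, `alpha`
#'   (`edge_type` is `"self"` for structural self-loops).
#' @export
attention_coefficients <- function(net, x, params, config, layer = 1L, head = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  if (anyNA(x) || any(!is.finite(x))) abort("Node features contain non-finite values.")
  if (ncol(x) != config$layer_in[layer]) {
    abort(sprintf("Layer %d expects %d input columns, got %d.",
                  layer, config$layer_in[layer], ncol(x)))
  }
  ea <- edge_arrays(net)
  lp <- params$layers[[layer]]
  c_type <- drop(lp$edge_embed %*% lp$edge_proj)
  hc <- head_forward(x, ea, lp$heads[[head]], c_type, config$leaky_slope)
  vocab <- c(net$edge_type_vocab, "self")
  tibble(source = net$nodes[ea$src], target = net$nodes[ea$dst],
         edge_type = vocab[ea$type], alpha = unname(hc$alpha))
}
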