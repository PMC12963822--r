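# Analytic backpropagation for the three-layer attention model, written
# against the caches produced by gat_forward_cached(). Gradients are
# returned in the same nested structure as the parameters (running
# batch-norm statistics get zero gradient; they are state, not weights).

# Numerically stable masked binary cross-entropy from logits.
# Returns the mean loss over `mask` and the gradient w.r.t. every logit.
bce_masked <- function(logit, y, mask) {
  z <- logit[mask]
  yl <- y[mask]
  loss <- mean(pmax(z, 0) - yl * z + log1p(exp(-abs(z))))
  dlogit <- numeric(length(logit))
  dlogit[mask] <- (sigmoid(z) - yl) / length(z)
  list(loss = loss, dlogit = dlogit)
}

zero_like <- function(params) {
  rapply(unclass(params), function(x) x * 0, how = "replace")
}

head_backward <- function(d_out, x, ea, hp, c_type, slope, hc) {
  z <- hc$z
  alpha <- hc$alpha
  d_msg <- d_out[ea$dst, , drop = FALSE]
  z_src <- z[ea$src, , drop = FALSE]
  d_alpha <- rowSums(d_msg * z_src)
  dz <- seg_sum_mat(ea$agg_src, d_msg * alpha)
  sdot <- seg_sum_vec(ea$agg_dst, alpha * d_alpha)
  de <- alpha * (d_alpha - sdot[ea$dst])
  dlog <- de * (slope + (1 - slope) * (hc$logit > 0))
  ds_dst <- seg_sum_vec(ea$agg_dst, dlog)
  dt_src <- seg_sum_vec(ea$agg_src, dlog)
  du <- seg_sum_vec(ea$agg_type, dlog)
  dz <- dz + outer(ds_dst, hp$a_dst) + outer(dt_src, hp$a_src)
  list(grad = list(W = crossprod(x, dz),
                   a_src = drop(crossprod(z, dt_src)),
                   a_dst = drop(crossprod(z, ds_dst)),
                   a_edge = sum(dlog * c_type[ea$type]),
                   bias = colSums(d_out)),
       dx = dz %*% t(hp$W),
       dc = hp$a_edge * du)
}

layer_backward <- function(d_out, ea, lp, config, lc) {
  d_in <- 0
  dc_total <- 0
  grads_heads <- vector("list", length(lp$heads))
  d <- ncol(lc$heads[[1]]$out)
  for (h in seq_along(lp$heads)) {
    cols <- ((h - 1L) * d + 1L):(h * d)
    hb <- head_backward(d_out[, cols, drop = FALSE], lc$x, ea, lp$heads[[h]],
                        lc$c_type, config$leaky_slope, lc$heads[[h]])
    grads_heads[[h]] <- hb$grad
    d_in <- d_in + hb$dx
    dc_total <- dc_total + hb$dc
  }
  list(grad = list(heads = grads_heads,
                   edge_embed = outer(dc_total, lp$edge_proj),
                   edge_proj = drop(crossprod(lp$edge_embed, dc_total))),
       dx = d_in)
}

bn_backward <- function(dy, bnc, gamma) {
  xhat <- bnc$xhat
  n <- nrow(xhat)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- mul_cols(dy, gamma)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- mul_cols(add_cols(dxhat, -m1) - mul_cols(xhat, m2), 1 / bnc$s)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

gat_backward <- function(ea, fw, dlogit, params, config) {
  grads <- zero_like(params)
  d_out <- matrix(dlogit, ncol = 1L)
  for (l in 3:1) {
    cache <- fw$caches[[l]]
    lb <- layer_backward(d_out, ea, params$layers[[l]], config, cache$layer)
    grads$layers[[l]]$heads <- lb$grad$heads
    grads$layers[[l]]$edge_embed <- lb$grad$edge_embed
    grads$layers[[l]]$edge_proj <- lb$grad$edge_proj
    d_out <- lb$dx
    if (l > 1L) {
      prev <- fw$caches[[l - 1L]]
      if (!is.null(prev$mask)) d_out <- d_out * prev$mask
      d_out <- d_out * exp(pmin(prev$act_in, 0))  # ELU' (= 1 where input > 0)
      bb <- bn_backward(d_out, prev$bn, params$bn[[l - 1L]]$gamma)
      grads$bn[[l - 1L]]$gamma <- bb$dgamma
      grads$bn[[l - 1L]]$beta <- bb$dbeta
      d_out <- bb$dx
    }
  }
  grads
}

# Flat-vector view of the parameters, with a mask marking trainable
# entries (running batch-norm statistics are carried along but never
# updated by the optimizer).
flatten_params <- function(params) unlist(unclass(params), use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  out <- utils::relist(vec, unclass(skeleton))
  class(out) <- "gat_parameters"
  out
}

trainable_mask <- function(params) {
  ones <- rapply(unclass(params), function(x) x * 0 + 1, how = "replace")
  for (l in seq_along(ones$bn)) {
    ones$bn[[l]]$running_mean[] <- 0
    ones$bn[[l]]$running_var[] <- 0
  }
  ones$n_types <- 0
  unlist(ones, use.names = FALSE) == 1
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, mask, tc) {
  g <- grad + tc$weight_decay * theta
  g[!mask] <- 0
  state$t <- state$t + 1L
  state$m <- tc$beta1 * state$m + (1 - tc$beta1) * g
  state$v <- tc$beta2 * state$v + (1 - tc$beta2) * g^2
  mhat <- state$m / (1 - tc$beta1^state$t)
  vhat <- state$v / (1 - tc$beta2^state$t)
  step <- tc$learning_rate * mhat / (sqrt(vhat) + tc$adam_eps)
  theta[mask] <- theta[mask] - step[mask]
  list(theta = theta, state = state)
}
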