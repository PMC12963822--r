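#' Stratified train/validation split over (gene, dataset) samples
#'
#' Samples are stratified by dataset and label so both the dataset mix and
#' the positive rate are maintained in the validation set. Within each
#' stratum the validation share is `round(val_fraction * stratum size)`
#' with exact .5 ties resolved toward the floor; a stratum too small to
#' contribute a validation sample goes entirely to training with a warning.
#'
#' @param samples A tibble with columns `gene_id`, `dataset_id`, `label`.
#' @param val_fraction Validation fraction, strictly in (0, 1).
#' @param seed Integer seed for the within-stratum shuffle.
#' @return The input tibble with a `.split` column (`"train"` /
#'   `"validation"`); the two sets are disjoint and exhaustive.
#' @export
stratified_split <- function(samples, val_fraction = 0.2, seed = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("gene_id", "dataset_id", "label") %in% names(samples)))
  val_fraction <- assert_fraction(val_fraction, "val_fraction")
  half_down_round <- function(x) {
    # round() is banker's; the rule here sends exact .5 down
    ifelse(abs(x - floor(x) - 0.5) < 1e-9, floor(x), round(x))
  }
  with_seed_if(seed, {
    out <- samples |>
      group_by(.data$dataset_id, .data$label) |>
      group_modify(function(df, key) {
        n_val <- half_down_round(val_fraction * nrow(df))
        df$.split <- "train"
        if (n_val == 0L) {
          warn(sprintf("Stratum dataset=%s label=%s too small for validation; all in train.",
                       key$dataset_id, key$label))
        } else {
          df$.split[sample.int(nrow(df), n_val)] <- "validation"
        }
        df
      }) |>
      ungroup()
    # restore the caller's row order
    key_in <- paste(samples$gene_id, samples$dataset_id, samples$label)
    key_out <- paste(out$gene_id, out$dataset_id, out$label)
    out[match(key_in, key_out), , drop = FALSE]
  })
}

#' Generic early-stopping training loop
#'
#' Drives any epoch-based optimization: each epoch `step_fn(epoch)` runs
#' the updates and returns the training loss, then `eval_fn(epoch)` returns
#' `list(loss = validation loss, state = snapshot)`. The loop keeps the
#' snapshot of the minimum-validation-loss epoch and terminates at the
#' earlier of `max_epochs` or `patience` consecutive epochs without
#' improvement (a run whose last improvement is at epoch k stops exactly at
#' epoch k + patience).
#'
#' @param step_fn,eval_fn Functions of the epoch index.
#' @param max_epochs,patience Loop bounds; see [train_config()].
#' @return A list: `best_state`, `best_epoch`, `stopped_epoch`, `history`
#'   (tibble `epoch, train_loss, val_loss`).
#' @export
early_stopping_loop <- function(step_fn, eval_fn, max_epochs, patience) {
  best_loss <- Inf
  best_state <- NULL
  best_epoch <- 0L
  history <- vector("list", max_epochs)
  epoch <- 0L
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    train_loss <- step_fn(epoch)
    ev <- eval_fn(epoch)
    if (!is.finite(train_loss) || !is.finite(ev$loss)) {
      abort(sprintf("Non-finite loss at epoch %d; training diverged.", epoch))
    }
    history[[epoch]] <- tibble(epoch = epoch, train_loss = train_loss,
                               val_loss = ev$loss)
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_state <- ev$state
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= patience) break
  }
  list(best_state = best_state, best_epoch = best_epoch, stopped_epoch = epoch,
       history = list_rbind(history[!vapply(history, is.null, TRUE)]))
}

#' Train the attention model on one or more MeRIP-seq datasets
#'
#' Each dataset is one full-graph training sample: per epoch the model runs
#' one forward/backward pass per dataset (shared parameters, shared PPI
#' topology, dataset-specific features and labels) with an Adam update
#' after each, and the epoch's training/validation losses are the average
#' masked binary cross-entropy across datasets. Losses are masked to the
#' stratified (gene, dataset) split — the standard transductive protocol.
#' The returned parameters are those of the minimum-validation-loss epoch.
#'
#' @param features A standardized multi-dataset feature tibble (from
#'   [zscore_by_dataset()], carrying its `"scaling"` attribute).
#' @param net A `ppi_network`.
#' @param config A [gat_config()].
#' @param train_cfg A [train_config()]; its `seed` governs the split,
#'   initialization and dropout.
#' @return A `gat_fit` object: `params` (best epoch), `config`,
#'   `train_config`, `history`, `best_epoch`, `stopped_epoch`, `net_nodes`,
#'   `split`, `n_dropped_features`.
#' @export
gat_train <- function(features, net, config = gat_config(),
                      train_cfg = train_config()) {
  stopifnot(inherits(net, "ppi_network"), inherits(config, "gat_config"),
            inherits(train_cfg, "train_config"))
  datasets <- unique(features$dataset_id)
  if (length(datasets) == 0L) abort("No datasets in `features`.")

  split <- stratified_split(
    features |> select("gene_id", "dataset_id", "label"),
    val_fraction = train_cfg$val_fraction, seed = train_cfg$seed)

  ea <- edge_arrays(net)
  node_of <- function(genes) match(genes, net$nodes)
  data <- lapply(datasets, function(d) {
    al <- align_features(net, features, d)
    sp <- split |> filter(.data$dataset_id == d)
    train_nodes <- node_of(sp$gene_id[sp$.split == "train"])
    val_nodes <- node_of(sp$gene_id[sp$.split == "validation"])
    train_mask <- sort(unique(c(train_nodes[!is.na(train_nodes)],
                                which(!net$nodes %in% sp$gene_id))))
    list(x = al$x, y = al$y,
         train_mask = train_mask,
         val_mask = sort(val_nodes[!is.na(val_nodes)]),
         dropped = al$dropped)
  })
  names(data) <- datasets
  n_dropped <- sum(lengths(lapply(data, `[[`, "dropped")))

  with_seed_if(train_cfg$seed, {
    params <- init_gat_parameters(config, length(net$edge_type_vocab),
                                  seed = NULL)
    theta <- flatten_params(params)
    mask <- trainable_mask(params)
    opt <- adam_init(length(theta))
    cur <- params

    step_fn <- function(epoch) {
      losses <- numeric(length(data))
      for (i in seq_along(data)) {
        d <- data[[i]]
        fw <- gat_forward_cached(ea, d$x, cur, config, train = TRUE)
        cur <<- fw$params  # running batch-norm statistics advance
        lo <- bce_masked(fw$logit, d$y, d$train_mask)
        grads <- gat_backward(ea, fw, lo$dlogit, cur, config)
        st <- adam_step(flatten_params(cur), flatten_params(grads), opt, mask,
                        train_cfg)
        opt <<- st$state
        cur <<- unflatten_params(st$theta, cur)
        losses[i] <- lo$loss
      }
      mean(losses)
    }
    eval_fn <- function(epoch) {
      losses <- vapply(data, function(d) {
        fw <- gat_forward_cached(ea, d$x, cur, config, train = FALSE)
        if (length(d$val_mask) == 0L) return(NA_real_)
        bce_masked(fw$logit, d$y, d$val_mask)$loss
      }, numeric(1))
      list(loss = mean(losses, na.rm = TRUE), state = cur)
    }

    loop <- early_stopping_loop(step_fn, eval_fn, train_cfg$max_epochs,
                                train_cfg$patience)
  })

  structure(
    list(params = loop$best_state, config = config, train_config = train_cfg,
         history = loop$history, best_epoch = loop$best_epoch,
         stopped_epoch = loop$stopped_epoch, net_nodes = net$nodes,
         split = split, n_dropped_features = n_dropped),
    class = "gat_fit")
}

#' @export
print.gat_fit <- function(x, ...) {
  cat(sprintf("<gat_fit> %d genes, stopped at epoch %d (best epoch %d, val loss %.4f)\n",
              length(x$net_nodes), x$stopped_epoch, x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Score genes with a trained model
#'
#' Runs a deterministic eval-mode forward pass per dataset and averages
#' each gene's score over the datasets in which its features were observed
#' (genes present only through imputation are averaged over all datasets).
#' Min-Max and Z-score normalized columns are added; a constant score
#' vector maps to 0.5 (Min-Max) and 0 (Z).
#'
#' @param fit A `gat_fit`.
#' @param net The `ppi_network` used in training.
#' @param features The standardized feature tibble.
#' @return A score tibble: `gene_id, raw_score, minmax_score, z_score,
#'   rank`, sorted by descending raw score (gene-id tie-break), ranks
#'   1-based.
#' @export
score_genes <- function(fit, net, features) {
  stopifnot(inherits(fit, "gat_fit"), inherits(net, "ppi_network"))
  datasets <- unique(features$dataset_id)
  ea <- edge_arrays(net)
  score_mat <- vapply(datasets, function(d) {
    al <- align_features(net, features, d)
    gat_forward_cached(ea, al$x, fit$params, fit$config, train = FALSE)$score
  }, numeric(length(net$nodes)))
  score_mat <- matrix(score_mat, nrow = length(net$nodes))
  observed <- vapply(datasets, function(d) {
    net$nodes %in% features$gene_id[features$dataset_id == d]
  }, logical(length(net$nodes)))
  observed <- matrix(observed, nrow = length(net$nodes))
  any_obs <- rowSums(observed) > 0
  w <- observed
  w[!any_obs, ] <- TRUE  # never-observed genes: average across all datasets
  raw <- rowSums(score_mat * w) / rowSums(w)

  tibble(gene_id = net$nodes, raw_score = raw) |>
    mutate(minmax_score = normalize_minmax(.data$raw_score),
           z_score = normalize_z(.data$raw_score)) |>
    arrange(desc(.data$raw_score), .data$gene_id) |>
    mutate(rank = seq_len(n()))
}

normalize_minmax <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}

normalize_z <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Top-scoring genes
#'
#' @param scores A score tibble (from [score_genes()]).
#' @param k How many genes (default 200, the usual candidate-set size).
#' @return Character vector of the `k` highest-raw-score gene ids
#'   (lexicographic tie-break).
#' @export
top_genes <- function(scores, k = 200L) {
  k <- assert_count(k, "k")
  scores |>
    arrange(desc(.data$raw_score), .data$gene_id) |>
    slice_head(n = k) |>
    pull("gene_id")
}

#' Save or load a model checkpoint
#'
#' The checkpoint is a JSON archive holding the flattened parameters, the
#' architecture configuration, the training seed and the network node
#' count; loading validates parameter shapes against the embedded
#' configuration.
#'
#' @param fit A `gat_fit`.
#' @param path Checkpoint path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a list with `params`, `config`, `seed`,
#'   `n_nodes`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "gat_fit"))
  cfg <- unclass(fit$config)
  payload <- list(
    config = cfg,
    n_edge_types = nrow(fit$params$layers[[1]]$edge_embed) - 1L,
    theta = flatten_params(fit$params),
    seed = fit$train_config$seed,
    n_nodes = length(fit$net_nodes),
    best_epoch = fit$best_epoch
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) abort(sprintf("Checkpoint does not exist: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(gat_config, payload$config[c("in_dim", "heads", "dim_per_head",
                                              "edge_embed_dim", "dropout",
                                              "attn_dropout", "leaky_slope",
                                              "bn_eps", "bn_momentum")])
  skeleton <- init_gat_parameters(cfg, payload$n_edge_types, seed = 0L)
  if (length(flatten_params(skeleton)) != length(payload$theta)) {
    abort("Checkpoint parameter vector does not match the embedded configuration.")
  }
  params <- unflatten_params(as.numeric(payload$theta), skeleton)
  check_shapes(params, cfg)
  list(params = params, config = cfg, seed = payload$seed,
       n_nodes = payload$n_nodes, best_epoch = payload$best_epoch)
}
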