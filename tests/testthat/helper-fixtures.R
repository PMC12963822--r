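# Shared fixtures: all built in code, none read from disk.

# Tiny named path / triangle / star graphs.
edge_records <- function(pairs, source = "db1") {
  tibble::tibble(gene_a = vapply(pairs, `[[`, "", 1L),
                 gene_b = vapply(pairs, `[[`, "", 2L),
                 source = source)
}

path_net <- function(genes = c("A", "B", "C")) {
  pairs <- Map(c, genes[-length(genes)], genes[-1])
  build_network(edge_records(pairs))
}

triangle_net <- function() {
  build_network(edge_records(list(c("A", "B"), c("B", "C"), c("A", "C"))))
}

star_net <- function(n_leaves = 4L) {
  leaves <- sprintf("L%d", seq_len(n_leaves))
  build_network(edge_records(Map(c, "HUB", leaves)))
}

# Small synthetic instance shared by the heavier unit tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_synthetic(
        synthetic_spec(n_genes = 120, n_datasets = 2, seed = 7))
    }
    cache
  }
})

# Standardized feature fixture for a hand-made network: every node gets
# features, labels alternate.
toy_features <- function(net, dataset_id = "d1", seed = 1) {
  withr::with_seed(seed, {
    n <- length(net$nodes)
    feats <- tibble::tibble(
      gene_id = net$nodes, dataset_id = dataset_id,
      expression_rpm = stats::rlnorm(n, log(5), 1),
      m5c_rpm = ifelse(seq_len(n) %% 2 == 0, stats::rlnorm(n, 0, 1) + 0.1, 0)
    ) |> dplyr::mutate(label = as.integer(m5c_rpm > 0))
    zscore_by_dataset(feats)
  })
}

# Independent scalar reimplementation of one attention head, used as the
# oracle for attention_coefficients(): plain loops, no shared code paths.
reference_attention <- function(net, x, params, config, layer, head) {
  n <- length(net$nodes)
  self_type <- length(net$edge_type_vocab) + 1L
  hp <- params$layers[[layer]]$heads[[head]]
  lp <- params$layers[[layer]]
  out <- list()
  for (i in seq_len(n)) {
    src <- c(net$edges$from[net$edges$to == i], i)
    typ <- c(net$edges$type[net$edges$to == i], self_type)
    logits <- numeric(length(src))
    for (e in seq_along(src)) {
      whi <- as.numeric(x[i, , drop = FALSE] %*% hp$W)
      whj <- as.numeric(x[src[e], , drop = FALSE] %*% hp$W)
      edge_term <- hp$a_edge * sum(lp$edge_embed[typ[e], ] * lp$edge_proj)
      z <- sum(hp$a_dst * whi) + sum(hp$a_src * whj) + edge_term
      logits[e] <- if (z > 0) z else config$leaky_slope * z
    }
    alpha <- exp(logits - max(logits))
    alpha <- alpha / sum(alpha)
    out[[i]] <- tibble::tibble(source = net$nodes[src], target = net$nodes[i],
                               alpha = alpha)
  }
  dplyr::bind_rows(out)
}

# Brute-force AUROC by pair counting (ties count half).
pair_count_auroc <- function(scores, positives) {
  pos <- scores$raw_score[scores$gene_id %in% positives]
  neg <- scores$raw_score[!scores$gene_id %in% positives]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
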