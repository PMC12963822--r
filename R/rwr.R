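#' Random walk with restart over the PPI network
#'
#' Iterates \eqn{p^{(t+1)} = (1-r)\,M p^{(t)} + r\,p_0} where `M` is the
#' column-stochastic (degree-normalized) adjacency of the undirected graph
#' and \eqn{p_0} is uniform over the seed genes, until the L1 change drops
#' below `tolerance`. Mass flowing into degree-0 (dangling) nodes is
#' returned through the restart vector, so the score vector remains a
#' probability distribution at every iteration. Because every interaction
#' is stored as a symmetric pair of unit-weight directed edges, this equals
#' normalization by out-degree.
#'
#' @param net A `ppi_network`.
#' @param seed_genes Character vector of seed gene symbols (all must exist
#'   in the network).
#' @param restart_prob Restart probability `r` in (0, 1]; default 0.7.
#' @param tolerance L1 convergence threshold (default 1e-8).
#' @param max_iter Iteration cap (default 10000); exceeding it is an error.
#' @return A tibble `gene_id, score` in node order; scores sum to 1.
#' @export
rwr <- function(net, seed_genes, restart_prob = 0.7, tolerance = 1e-8,
                max_iter = 10000L) {
  stopifnot(inherits(net, "ppi_network"))
  if (restart_prob <= 0 || restart_prob > 1) abort("`restart_prob` must lie in (0, 1].")
  seed_genes <- unique(clean_symbols(seed_genes))
  unknown <- setdiff(seed_genes, net$nodes)
  if (length(unknown)) {
    abort(sprintf("Seed gene(s) not in the network: %s.",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  n <- length(net$nodes)
  p0 <- numeric(n)
  p0[match(seed_genes, net$nodes)] <- 1 / length(seed_genes)

  m <- rwr_transition(net)
  dangling <- net$degree == 0
  p <- p0
  for (it in seq_len(max_iter)) {
    lost <- sum(p[dangling])
    p_new <- as.numeric((1 - restart_prob) * (m %*% p)) +
      (restart_prob + (1 - restart_prob) * lost) * p0
    if (sum(abs(p_new - p)) < tolerance) {
      return(tibble(gene_id = net$nodes, score = p_new))
    }
    p <- p_new
  }
  abort(sprintf("RWR did not converge within %d iterations (tolerance %g).",
                max_iter, tolerance))
}

# Column-stochastic transition matrix A %*% diag(1/deg); zero columns for
# dangling nodes (their mass is re-routed through the restart vector).
rwr_transition <- function(net) {
  n <- length(net$nodes)
  e <- net$edges
  inv_deg <- ifelse(net$degree > 0, 1 / net$degree, 0)
  Matrix::sparseMatrix(i = e$to, j = e$from, x = inv_deg[e$from],
                       dims = c(n, n))
}

#' Sample modified genes as propagation seeds
#'
#' Uniform sample without replacement from the genes carrying a retained
#' m5C peak (`label == 1`) in any dataset of the feature table.
#'
#' @param features A feature tibble with `gene_id`, `label`.
#' @param n Number of seed genes.
#' @param seed Integer seed for reproducible sampling.
#' @return Character vector of `n` gene symbols.
#' @export
sample_seed_genes <- function(features, n, seed = NULL) {
  n <- assert_count(n, "n")
  positives <- sort(unique(features$gene_id[features$label == 1]))
  if (length(positives) < n) {
    abort(sprintf("Requested %d seed genes but only %d modified genes are available.",
                  n, length(positives)))
  }
  with_seed_if(seed, sample(positives, n))
}
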