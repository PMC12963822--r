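#' Area under the ROC curve against a ground-truth gene set
#'
#' Rank-based AUROC with ties counted half — the Mann-Whitney U statistic
#' normalized by \eqn{n_+ n_-}: the probability that a random truth gene
#' outscores a random non-truth gene.
#'
#' @param scores A data frame with `gene_id` and a numeric score column.
#' @param truth Character vector of ground-truth (positive) gene symbols;
#'   intersected with the scored universe, which must contain at least one
#'   positive and one negative.
#' @param score_col Name of the score column (default `"raw_score"`).
#' @return A single number in `[0, 1]`.
#' @export
auroc <- function(scores, truth, score_col = "raw_score") {
  stopifnot(is.data.frame(scores), score_col %in% names(scores))
  s <- scores[[score_col]]
  pos <- scores$gene_id %in% clean_symbols(truth)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Degenerate ground truth: need at least one positive and one negative gene.")
  }
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Degree-based candidate filter
#'
#' Ranks non-seed genes by a score computed solely from degree information
#' — `degree(gene) * mean(seed degrees)` — with lexicographic gene-id
#' tie-break, and returns the top `k`. Because the inputs are degrees only,
#' the output is exactly invariant under any degree-preserving
#' transformation of the network, which is what makes this filter
#' perfectly stable across degree-preserving random-network ensembles (and
#' fast: no iterative propagation per network).
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of seed genes (must be network nodes).
#' @param k Candidate-set size; at most the number of non-seed genes.
#' @return Character vector of `k` candidate gene symbols.
#' @export
degree_based_candidate_filter <- function(net, seeds, k = 200L) {
  stopifnot(inherits(net, "ppi_network"))
  seeds <- unique(clean_symbols(seeds))
  if (length(seeds) == 0L) abort("`seeds` must contain at least one gene.")
  unknown <- setdiff(seeds, net$nodes)
  if (length(unknown)) {
    abort(sprintf("Seed gene(s) not in the network: %s.",
                  paste(head(unknown, 5L), collapse = ", ")))
  }
  k <- assert_count(k, "k")
  candidates <- setdiff(net$nodes, seeds)
  if (k > length(candidates)) {
    abort(sprintf("k = %d exceeds the %d non-seed genes.", k, length(candidates)))
  }
  seed_deg_mean <- mean(net$degree[seeds])
  score <- net$degree[candidates] * seed_deg_mean
  ord <- order(-score, candidates)
  candidates[ord][seq_len(k)]
}

#' Two-ensemble robustness protocol over degree-preserving random networks
#'
#' Reproduces the stability benchmark: two independent ensembles of
#' degree-preserving randomizations of the input network are generated; on
#' every network each method derives a top-`k` candidate set from the same
#' seed genes (degree filter: [degree_based_candidate_filter()]; RWR:
#' top-`k` propagation scores excluding seeds); each ensemble is collapsed
#' to a consensus set (genes present in at least `consensus` of its
#' per-network candidate sets) and the per-method result is the size of
#' the symmetric difference between the two consensus sets.
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of seed genes, e.g. from
#'   [sample_seed_genes()].
#' @param n_networks Networks per ensemble (default 100).
#' @param k Candidate-set size (default 200).
#' @param methods Which methods to benchmark.
#' @param consensus Consensus membership threshold (default 0.5).
#' @param restart_prob RWR restart probability.
#' @param n_swaps Swaps per randomization (default 10x the edge count).
#' @param seed Integer seed; the two ensembles use independent derived
#'   seeds.
#' @return A `robustness_result` tibble: one row per method with
#'   `n_differing` and list-columns `consensus_a`, `consensus_b`,
#'   `sets_a`, `sets_b` (per-network candidate sets, retained for audit).
#' @export
robustness_protocol <- function(net, seeds, n_networks = 100L, k = 200L,
                                methods = c("degree_filter", "rwr"),
                                consensus = 0.5, restart_prob = 0.7,
                                n_swaps = NULL, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"))
  methods <- match.arg(methods, several.ok = TRUE)
  n_networks <- assert_count(n_networks, "n_networks")

  candidate_sets <- function(method, nets) {
    lapply(nets, function(g) {
      switch(method,
        degree_filter = degree_based_candidate_filter(g, seeds, k),
        rwr = {
          sc <- rwr(g, seeds, restart_prob = restart_prob)
          sc <- sc |> filter(!.data$gene_id %in% seeds)
          sc$gene_id[order(-sc$score, sc$gene_id)][seq_len(k)]
        })
    })
  }
  consensus_set <- function(sets) {
    counts <- table(unlist(sets))
    sort(names(counts)[counts >= consensus * length(sets)])
  }

  ens_seed <- with_seed_if(seed, sample.int(.Machine$integer.max, 2L))
  ensembles <- lapply(1:2, function(i) {
    with_seed_if(ens_seed[i], {
      lapply(seq_len(n_networks), function(j) {
        degree_preserving_randomize(net, n_swaps = n_swaps, seed = NULL)
      })
    })
  })

  rows <- lapply(methods, function(m) {
    sets_a <- candidate_sets(m, ensembles[[1]])
    sets_b <- candidate_sets(m, ensembles[[2]])
    a <- consensus_set(sets_a)
    b <- consensus_set(sets_b)
    tibble(method = m,
           n_differing = length(union(setdiff(a, b), setdiff(b, a))),
           consensus_a = list(a), consensus_b = list(b),
           sets_a = list(sets_a), sets_b = list(sets_b))
  })
  out <- list_rbind(rows)
  class(out) <- c("robustness_result", class(out))
  out
}

#' Hypergeometric over-representation test
#'
#' One-sided hypergeometric tail p-value for the overlap between a
#' top-gene set and each supplied gene set (both intersected with the
#' universe), with Benjamini-Hochberg adjustment.
#'
#' @param top_genes Character vector, a subset of `universe`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all scored genes.
#' @return A tibble `set, set_size, overlap, p_value, q_value`, ordered by
#'   increasing p-value.
#' @export
over_representation <- function(top_genes, gene_sets, universe) {
  universe <- unique(clean_symbols(universe))
  if (length(universe) == 0L) abort("`universe` is empty.")
  top_genes <- intersect(unique(clean_symbols(top_genes)), universe)
  if (!is.list(gene_sets) || is.null(names(gene_sets))) {
    abort("`gene_sets` must be a named list of gene vectors.")
  }
  n_u <- length(universe)
  n_top <- length(top_genes)
  rows <- imap(gene_sets, function(set, name) {
    set <- intersect(unique(clean_symbols(set)), universe)
    ov <- length(intersect(set, top_genes))
    p <- stats::phyper(ov - 1L, length(set), n_u - length(set), n_top,
                       lower.tail = FALSE)
    tibble(set = name, set_size = length(set), overlap = ov, p_value = p)
  })
  list_rbind(rows) |>
    mutate(q_value = stats::p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value, .data$set)
}

#' Wall-clock timing harness
#'
#' Times each supplied method callable over `repetitions` runs and reports
#' the median and interquartile range. Timings are reported, never
#' asserted as ratios: wall-clock factors are hardware-dependent.
#'
#' @param methods Named list of zero-argument functions.
#' @param repetitions Runs per method (default 3).
#' @param net Optional `ppi_network`; if given, its size is recorded.
#' @return A list with `timings` (tibble `method, rep, seconds`) and
#'   `summary` (tibble `method, median_s, iqr_s, n_nodes, n_edges`).
#' @export
timing_harness <- function(methods, repetitions = 3L, net = NULL) {
  stopifnot(is.list(methods), !is.null(names(methods)))
  repetitions <- assert_count(repetitions, "repetitions")
  timings <- list_rbind(imap(methods, function(f, name) {
    secs <- vapply(seq_len(repetitions), function(i) {
      unname(system.time(f())[["elapsed"]])
    }, numeric(1))
    tibble(method = name, rep = seq_len(repetitions), seconds = secs)
  }))
  summary <- timings |>
    group_by(.data$method) |>
    summarise(median_s = median(.data$seconds),
              iqr_s = stats::IQR(.data$seconds), .groups = "drop") |>
    mutate(n_nodes = if (is.null(net)) NA_integer_ else length(net$nodes),
           n_edges = if (is.null(net)) NA_integer_ else nrow(net$edges) / 2L)
  list(timings = timings, summary = summary)
}
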