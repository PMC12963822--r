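#' Build a merged, typed, directed PPI network
#'
#' Interactions from one or more source databases are deduplicated over
#' unordered gene pairs, and every unique pair is expanded into two
#' directed, unit-weight edges so that message passing can run in both
#' directions while preserving the undirected biology. When a pair is
#' reported by several sources, its edge type follows a fixed precedence
#' order (first source wins). Node order is lexicographic so runs are
#' reproducible across platforms.
#'
#' @param records An edge-record tibble from [read_edge_list()] (columns
#'   `gene_a`, `gene_b`, `source`).
#' @param source_precedence Optional character vector declaring edge-type
#'   precedence; defaults to sources in order of first appearance.
#' @return A `ppi_network` object: list with `nodes` (sorted symbols),
#'   `edges` (tibble `from, to, type, weight` of directed edges, indices
#'   into `nodes`), `edge_type_vocab`, and `degree` (undirected, named by
#'   node).
#' @export
build_network <- function(records, source_precedence = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) abort("build_network() needs at least one interaction record.")
  rec <- records |>
    mutate(gene_a = clean_symbols(.data$gene_a), gene_b = clean_symbols(.data$gene_b)) |>
    filter(.data$gene_a != .data$gene_b)
  if (nrow(rec) == 0L) abort("All records were self-interactions; nothing to build.")
  if (!"source" %in% names(rec)) rec$source <- "ppi"

  vocab <- source_precedence %||% unique(rec$source)
  unknown <- setdiff(unique(rec$source), vocab)
  if (length(unknown)) {
    abort(sprintf("Sources absent from `source_precedence`: %s.",
                  paste(unknown, collapse = ", ")))
  }

  pairs <- rec |>
    mutate(u = pmin(.data$gene_a, .data$gene_b),
           v = pmax(.data$gene_a, .data$gene_b),
           prec = match(.data$source, vocab)) |>
    group_by(.data$u, .data$v) |>
    summarise(type = min(.data$prec), .groups = "drop")

  nodes <- sort(unique(c(pairs$u, pairs$v)))
  ui <- match(pairs$u, nodes)
  vi <- match(pairs$v, nodes)
  edges <- tibble(
    from = c(ui, vi), to = c(vi, ui),
    type = rep(pairs$type, 2L), weight = 1
  ) |>
    arrange(.data$to, .data$from)

  deg <- tabulate(c(ui, vi), nbins = length(nodes))
  structure(
    list(nodes = nodes, edges = edges, edge_type_vocab = vocab,
         degree = setNames(as.integer(deg), nodes)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d genes, %d undirected interactions (%d directed edges)\n",
              length(x$nodes), nrow(x$edges) / 2L, nrow(x$edges)))
  cat(sprintf("  edge types: %s\n", paste(x$edge_type_vocab, collapse = ", ")))
  invisible(x)
}

#' Validate the structural invariants of a PPI network
#'
#' Checks that every directed edge has its reverse with identical type and
#' weight, that all weights equal 1, that the stored graph is simple (no
#' self-edges, no duplicate ordered pairs) and that the degree table matches
#' the edge list.
#'
#' @param net A `ppi_network`.
#' @return `net`, invisibly; aborts with a message on the first violated
#'   invariant.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  e <- net$edges
  if (any(e$from == e$to)) abort("Network invariant violated: self-edge present.")
  if (any(e$weight != 1)) abort("Network invariant violated: non-unit edge weight.")
  key <- paste(e$from, e$to)
  if (anyDuplicated(key)) abort("Network invariant violated: duplicate directed edge.")
  rev_key <- paste(e$to, e$from)
  m <- match(rev_key, key)
  if (anyNA(m)) abort("Network invariant violated: unpaired directed edge.")
  if (any(e$type[m] != e$type)) abort("Network invariant violated: reverse edge type differs.")
  deg <- tabulate(e$to, nbins = length(net$nodes))
  if (!identical(as.integer(deg), as.integer(unname(net$degree)))) {
    abort("Network invariant violated: degree table out of sync with edges.")
  }
  invisible(net)
}

# Undirected igraph view (one edge per unordered pair), keeping isolated nodes.
ppi_igraph <- function(net) {
  und <- net$edges |> filter(.data$from < .data$to)
  igraph::graph_from_edgelist(cbind(und$from, und$to), directed = FALSE) |>
    igraph::add_vertices(nv = max(0L, length(net$nodes) - max(c(und$from, und$to, 0L))))
}

#' Degree-preserving network randomization
#'
#' Rewires the undirected interaction set by repeated double-edge swaps
#' (swaps creating self-edges or duplicate edges are rejected and retried),
#' then re-expands to paired directed edges. The node set, edge count and
#' per-node degree sequence are preserved exactly. Edge-type identities are
#' not preserved by rewiring: all randomized edges carry a single
#' `"rewired"` type (the null model is topological; its consumers read only
#' degrees and adjacency).
#'
#' @param net A `ppi_network` with at least 2 undirected edges.
#' @param n_swaps Number of attempted swaps; defaults to 10 times the
#'   undirected edge count.
#' @param seed Optional integer for reproducible rewiring.
#' @return A new `ppi_network`.
#' @export
degree_preserving_randomize <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  m <- nrow(net$edges) / 2L
  if (m < 2L) abort("Randomization needs at least 2 independent undirected edges.")
  n_swaps <- n_swaps %||% (10L * m)
  if (n_swaps <= 0) abort("`n_swaps` must be a positive integer.")
  g <- ppi_igraph(net)
  if (igraph::vcount(g) < length(net$nodes)) {
    g <- igraph::add_vertices(g, length(net$nodes) - igraph::vcount(g))
  }
  gr <- with_seed_if(seed, igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                                    niter = n_swaps)))
  el <- igraph::as_edgelist(gr, names = FALSE)
  u <- pmin(el[, 1], el[, 2]); v <- pmax(el[, 1], el[, 2])
  ord <- order(u, v)
  u <- u[ord]; v <- v[ord]
  edges <- tibble(from = c(u, v), to = c(v, u), type = 1L, weight = 1) |>
    arrange(.data$to, .data$from)
  out <- structure(
    list(nodes = net$nodes, edges = edges, edge_type_vocab = "rewired",
         degree = setNames(as.integer(tabulate(c(u, v), nbins = length(net$nodes))),
                           net$nodes)),
    class = "ppi_network"
  )
  validate_network(out)
}

#' Align standardized features to a network's node order
#'
#' Produces the model input for one dataset: a node-by-2 matrix of
#' standardized (expression, m5C) features and a 0/1 label vector in the
#' network's node order. Network genes missing from the feature table are
#' imputed with the standardized value corresponding to 0 RPM under that
#' dataset's scaling and labeled 0; feature genes absent from the network
#' are dropped and counted.
#'
#' @param net A `ppi_network`.
#' @param features A standardized feature tibble (must carry the
#'   `"scaling"` attribute written by [zscore_by_dataset()]).
#' @param dataset_id Which dataset to align.
#' @return A list: `x` (numeric matrix, rownames = nodes, columns
#'   `expression_z`, `m5c_z`), `y` (integer labels), `dropped` (character
#'   vector of feature genes not in the network).
#' @export
align_features <- function(net, features, dataset_id) {
  stopifnot(inherits(net, "ppi_network"), is.data.frame(features))
  scaling <- attr(features, "scaling")
  if (is.null(scaling) || !all(c("expression_z", "m5c_z") %in% names(features))) {
    abort("`features` is not standardized (missing z columns or the \"scaling\" attribute); run zscore_by_dataset() first.")
  }
  feat <- features |> filter(.data$dataset_id == .env$dataset_id)
  if (nrow(feat) == 0L) abort(sprintf("No features found for dataset %s.", dataset_id))
  sc <- scaling |> filter(.data$dataset_id == .env$dataset_id)
  zero_expr_z <- if (sc$expression_sigma > 0) -sc$expression_mu / sc$expression_sigma else 0
  zero_m5c_z <- if (sc$m5c_sigma > 0) -sc$m5c_mu / sc$m5c_sigma else 0

  idx <- match(net$nodes, feat$gene_id)
  x <- cbind(
    expression_z = ifelse(is.na(idx), zero_expr_z, feat$expression_z[idx]),
    m5c_z = ifelse(is.na(idx), zero_m5c_z, feat$m5c_z[idx])
  )
  rownames(x) <- net$nodes
  y <- ifelse(is.na(idx), 0L, feat$label[idx])
  dropped <- setdiff(feat$gene_id, net$nodes)
  list(x = x, y = as.integer(y), dropped = dropped)
}

#' Serialize a PPI network to a directed-edge TSV
#'
#' The file starts with a `#types:` header enumerating the edge-type
#' vocabulary, followed by one row per directed edge:
#' `from_gene, to_gene, type, weight`.
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns the reconstructed `ppi_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste0("#types:\t", paste(net$edge_type_vocab, collapse = "\t")), path)
  readr::write_tsv(
    tibble(from = net$nodes[net$edges$from], to = net$nodes[net$edges$to],
           type = net$edge_type_vocab[net$edges$type], weight = net$edges$weight),
    path, col_names = TRUE, progress = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) abort(sprintf("Network file does not exist: %s", path))
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#types:")) abort("Network file lacks the '#types:' header.")
  vocab <- strsplit(sub("^#types:\\t?", "", header), "\t", fixed = TRUE)[[1]]
  tab <- readr::read_tsv(path, skip = 1L, show_col_types = FALSE, progress = FALSE)
  und <- tab |> filter(.data$from < .data$to)
  rec <- tibble(gene_a = und$from, gene_b = und$to, source = und$type)
  build_network(rec, source_precedence = vocab)
}
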