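#' Specification of a synthetic benchmark instance
#'
#' Describes the synthetic study conditions: a scale-free PPI-like graph
#' grown by preferential attachment, a planted set of functional genes
#' biased toward hubs and toward mutual adjacency (module structure), and
#' per-dataset (expression, m5C) feature pairs in which functional genes
#' carry elevated signal in both channels. The defaults emulate a
#' multi-dataset MeRIP-seq design at desk scale: 2000 genes, six datasets,
#' 30% modified genes per dataset, 5% planted functional genes.
#'
#' @param n_genes Number of genes (>= 10; default 2000).
#' @param attachment_edges Edges attached per new node during
#'   preferential-attachment growth (default 3).
#' @param n_datasets Number of emulated MeRIP-seq datasets (default 6).
#' @param frac_modified Expected label-1 fraction per dataset (default 0.3).
#' @param frac_functional Planted functional-gene fraction (default 0.05).
#' @param effect_size Log-scale mean shift of m5C (and half of it for
#'   expression) for functional genes, in units of `noise_sd` (default 2).
#' @param noise_sd Log-scale standard deviation of both channels (default 1).
#' @param hub_bias Strength of the preference for functional genes to be
#'   high-degree, in `[0, 1)` scale-free exponent units (default 0.5;
#'   0 = uniform).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 2000L, attachment_edges = 3L, n_datasets = 6L,
                           frac_modified = 0.3, frac_functional = 0.05,
                           effect_size = 2.0, noise_sd = 1.0, hub_bias = 0.5,
                           seed = 1L) {
  problems <- c(
    if (!is.numeric(n_genes) || n_genes < 10) "n_genes must be >= 10",
    if (!is.numeric(attachment_edges) || attachment_edges < 1)
      "attachment_edges must be >= 1",
    if (!is.numeric(n_datasets) || n_datasets < 1) "n_datasets must be >= 1",
    if (!is.numeric(frac_modified) || frac_modified <= 0 || frac_modified >= 1)
      "frac_modified must lie in (0, 1)",
    if (!is.numeric(frac_functional) || frac_functional <= 0 || frac_functional >= 1)
      "frac_functional must lie in (0, 1)",
    if (!is.numeric(effect_size) || effect_size < 0) "effect_size must be >= 0",
    if (!is.numeric(noise_sd) || noise_sd <= 0) "noise_sd must be > 0",
    if (!is.numeric(hub_bias) || hub_bias < 0) "hub_bias must be >= 0"
  )
  if (length(problems)) {
    abort(paste0("Invalid synthetic_spec: ", paste(problems, collapse = "; "), "."))
  }
  structure(list(n_genes = as.integer(n_genes),
                 attachment_edges = as.integer(attachment_edges),
                 n_datasets = as.integer(n_datasets),
                 frac_modified = frac_modified, frac_functional = frac_functional,
                 effect_size = effect_size, noise_sd = noise_sd,
                 hub_bias = hub_bias, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic network, features and planted ground truth
#'
#' Grows a scale-free graph (preferential attachment, no multi-edges),
#' plants functional genes with a hub bias and a preference for mutual
#' adjacency, then simulates per-dataset modification labels and
#' log-normal (expression, m5C) levels: functional genes are modified with
#' elevated probability and, when modified, their m5C level is shifted by
#' `effect_size` (expression by `effect_size / 2`) on the log scale.
#' Modified genes are truncated upward to 1.0 RPM expression and 0.1 RPM
#' m5C so every planted positive survives [filter_low_signal()]. The
#' returned features have been low-signal-filtered and Z-scored with the
#' package's own pipeline.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `network` (`ppi_network`), `features` (standardized
#'   multi-dataset feature tibble with `"scaling"` attribute), `truth`
#'   (character vector of planted functional genes), `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed_if(spec$seed, {
    genes <- sprintf("G%05d", seq_len(spec$n_genes))
    g <- igraph::sample_pa(spec$n_genes, m = spec$attachment_edges,
                           directed = FALSE, algorithm = "psumtree")
    el <- igraph::as_edgelist(g, names = FALSE)
    net <- build_network(tibble(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
                                source = "synthetic"))

    deg <- net$degree[genes]
    n_func <- max(2L, round(spec$frac_functional * spec$n_genes))
    truth <- plant_functional(net, genes, deg, n_func, spec$hub_bias)

    # modification enrichment of functional genes scales with the effect
    # size so the null construction (effect_size = 0) removes the signal
    # from the labels as well as from both channels
    p_func <- min(0.9, spec$frac_modified * (1 + spec$effect_size))
    p_background <- (spec$frac_modified - spec$frac_functional * p_func) /
      (1 - spec$frac_functional)
    p_background <- min(max(p_background, 0.01), 0.99)
    is_func <- genes %in% truth

    features <- list_rbind(lapply(seq_len(spec$n_datasets), function(d) {
      modified <- rbinom(spec$n_genes, 1L, ifelse(is_func, p_func, p_background))
      m5c <- numeric(spec$n_genes)
      on <- modified == 1L
      m5c[on] <- pmax(0.1, rlnorm(sum(on),
                                  meanlog = log(1) + spec$effect_size * spec$noise_sd *
                                    is_func[on],
                                  sdlog = spec$noise_sd))
      expr <- rlnorm(spec$n_genes,
                     meanlog = log(5) + (spec$effect_size / 2) * spec$noise_sd * is_func,
                     sdlog = spec$noise_sd)
      expr[on] <- pmax(1.0, expr[on])
      tibble(gene_id = genes, dataset_id = sprintf("sim%02d", d),
             expression_rpm = expr, m5c_rpm = m5c, label = modified)
    }))

    features <- features |> filter_low_signal() |> zscore_by_dataset()
    list(network = net, features = features, truth = sort(truth), spec = spec)
  })
}

# Sample functional genes: degree-weighted (deg^(2*hub_bias)) picks
# interleaved with uniform picks from the neighborhood of the current
# functional set, giving both hubness and module structure. hub_bias = 0
# removes both preferences (uniform sampling).
plant_functional <- function(net, genes, deg, n_func, hub_bias) {
  if (hub_bias == 0) return(sample(genes, n_func))
  w <- (pmax(deg, 1))^(2 * hub_bias)
  adj <- split(net$nodes[net$edges$to], net$nodes[net$edges$from])
  chosen <- character(0)
  first <- sample(genes, 1L, prob = w)
  chosen <- first
  while (length(chosen) < n_func) {
    nb <- setdiff(unique(unlist(adj[chosen], use.names = FALSE)), chosen)
    pick_neighbor <- length(nb) > 0 && runif(1) < 0.5
    if (pick_neighbor) {
      nxt <- if (length(nb) == 1L) nb else sample(nb, 1L, prob = w[match(nb, genes)])
    } else {
      rest <- setdiff(genes, chosen)
      nxt <- sample(rest, 1L, prob = w[match(rest, genes)])
    }
    chosen <- c(chosen, nxt)
  }
  chosen
}

#' Write a toy quantification fixture to disk
#'
#' Produces a BED6+3-style peak table and an expression TSV readable by
#' [read_quantification()], deliberately exercising every filter branch:
#' one gene with exactly two peaks (aggregation), rows at expression 0.99
#' and m5C 0.09 (both low-signal rejections), boundary rows at exactly
#' 1.0 / 0.1 RPM (kept), a peak with `log2_fc` just below `log2(1.5)` and
#' one with `p_value` just above 0.05 (differential-filter rejections),
#' plus `n_peaks` additional randomized well-formed peaks.
#'
#' @param dir Output directory (created if missing).
#' @param n_peaks Number of additional random peaks (>= 1).
#' @param spec A [synthetic_spec()] supplying noise level and seed.
#' @return A list with `peaks_path`, `expression_path`, `dataset_id`.
#' @export
make_toy_quantification <- function(dir = tempfile("toyquant"), n_peaks = 12L,
                                    spec = synthetic_spec()) {
  n_peaks <- assert_count(n_peaks, "n_peaks")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataset_id <- "toy01"
  with_seed_if(spec$seed, {
    fixed <- tibble(
      chrom = "chr1",
      start = seq(1000L, by = 1000L, length.out = 7L),
      end = seq(1200L, by = 1000L, length.out = 7L),
      gene_id = c("MULTI", "MULTI", "LOWEXP", "LOWM5C", "EDGECASE", "WEAKFC", "WEAKP"),
      m5c_rpm = c(0.2, 0.3, 5.0, 0.09, 0.1, 1.0, 1.0),
      strand = "+",
      log2_fc = c(0.7, 0.7, 0.7, 0.7, 0.7, log2(1.5) - 0.01, 1.0),
      p_value = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.06)
    )
    rnd_genes <- sprintf("TOY%03d", seq_len(n_peaks))
    rnd <- tibble(
      chrom = "chr2",
      start = seq(1000L, by = 1000L, length.out = n_peaks),
      end = seq(1300L, by = 1000L, length.out = n_peaks),
      gene_id = rnd_genes,
      m5c_rpm = round(rlnorm(n_peaks, 0, spec$noise_sd) + 0.1, 4),
      strand = sample(c("+", "-"), n_peaks, replace = TRUE),
      log2_fc = round(rnorm(n_peaks, 0, 1), 4),
      p_value = round(runif(n_peaks), 4)
    )
    peaks <- bind_rows(fixed, rnd) |> mutate(dataset_id = dataset_id)
    expr <- tibble(
      gene_id = unique(peaks$gene_id),
      expression_rpm = round(rlnorm(length(unique(peaks$gene_id)), log(5),
                                    spec$noise_sd) + 1, 4)
    ) |>
      mutate(expression_rpm = ifelse(.data$gene_id == "LOWEXP", 0.99,
                              ifelse(.data$gene_id == "EDGECASE", 1.0,
                                     .data$expression_rpm)))
  })
  peaks_path <- file.path(dir, "toy_peaks.tsv")
  expression_path <- file.path(dir, "toy_expression.tsv")
  readr::write_tsv(peaks |> select("chrom", "start", "end", "strand", "gene_id",
                                   "m5c_rpm", "log2_fc", "p_value", "dataset_id"),
                   peaks_path, progress = FALSE)
  readr::write_tsv(expr, expression_path, progress = FALSE)
  list(peaks_path = peaks_path, expression_path = expression_path,
       dataset_id = dataset_id)
}
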