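#' Aggregate multiple m5C peaks to one value per gene
#'
#' Genes commonly carry several called peaks; the model consumes one m5C
#' level per gene and dataset, so duplicate gene entries are collapsed by
#' summing their per-peak RPM (default) or taking the maximum.
#'
#' @param peaks A tibble of peak records (needs `gene_id`, `m5c_rpm`,
#'   `dataset_id`); all rows must share one `dataset_id`.
#' @param method `"sum"` (default) or `"max"`.
#' @return A tibble with columns `gene_id`, `m5c_rpm`, one row per gene.
#' @export
aggregate_peaks <- function(peaks, method = c("sum", "max")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) {
    return(tibble(gene_id = character(), m5c_rpm = numeric()))
  }
  if ("dataset_id" %in% names(peaks) && length(unique(peaks$dataset_id)) > 1L) {
    abort("aggregate_peaks() expects records from a single dataset; got mixed dataset_id.")
  }
  agg <- if (method == "sum") sum else max
  peaks |>
    group_by(.data$gene_id) |>
    summarise(m5c_rpm = agg(.data$m5c_rpm), .groups = "drop") |>
    arrange(.data$gene_id)
}

#' Assemble per-gene model features for one dataset
#'
#' Joins aggregated peak levels with expression levels over a gene universe
#' (typically the PPI network's node set). Genes with at least one peak get
#' `label = 1`; all other genes get `label = 0` with `m5c_rpm = 0`. Genes
#' absent from the expression table default to 0 RPM.
#'
#' @param peaks Peak records for one dataset (see [read_quantification()]).
#' @param expression Expression records for the same dataset.
#' @param genes Optional character vector fixing the gene universe (e.g.
#'   `network$nodes`); peak/expression genes outside it are still kept so
#'   that [align_features()] can report them.
#' @param aggregate Peak aggregation method, see [aggregate_peaks()].
#' @return A tibble with columns `gene_id, dataset_id, expression_rpm,
#'   m5c_rpm, label`.
#' @export
assemble_features <- function(peaks, expression, genes = NULL,
                              aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  dataset <- unique(c(peaks$dataset_id, expression$dataset_id))
  if (length(dataset) != 1L) {
    abort("assemble_features() expects peak and expression records from one dataset.")
  }
  peak_levels <- aggregate_peaks(peaks, aggregate)
  universe <- sort(unique(c(genes, peak_levels$gene_id, expression$gene_id)))
  tibble(gene_id = universe, dataset_id = dataset) |>
    left_join(peak_levels, by = "gene_id") |>
    left_join(select(expression, "gene_id", "expression_rpm"), by = "gene_id") |>
    mutate(m5c_rpm = ifelse(is.na(.data$m5c_rpm), 0, .data$m5c_rpm),
           expression_rpm = ifelse(is.na(.data$expression_rpm), 0, .data$expression_rpm),
           label = as.integer(.data$m5c_rpm > 0))
}

#' Filter weakly supported positives
#'
#' A peak-bearing gene is kept as a positive only if its expression is at
#' least `min_expression` RPM and its aggregated m5C level at least
#' `min_m5c` RPM (the filter removes strictly-below values, so the
#' boundary is kept). Genes failing either filter are demoted to negatives
#' (`label = 0`, `m5c_rpm` reset to 0) rather than deleted: the label
#' definition needs every network gene to remain as a `y = 0` node.
#'
#' @param features A feature tibble (from [assemble_features()]).
#' @param min_expression,min_m5c RPM thresholds; defaults 1.0 and 0.1.
#' @return The feature tibble with demotions applied; attribute `n_demoted`
#'   counts affected genes.
#' @export
filter_low_signal <- function(features, min_expression = 1.0, min_m5c = 0.1) {
  stopifnot(is.data.frame(features))
  demote <- features$label == 1L &
    (features$expression_rpm < min_expression | features$m5c_rpm < min_m5c)
  out <- features |>
    mutate(m5c_rpm = ifelse(demote, 0, .data$m5c_rpm),
           label = ifelse(demote, 0L, .data$label))
  attr(out, "n_demoted") <- sum(demote)
  out
}

#' Z-score standardize features within each dataset
#'
#' Expression and m5C channels are standardized to mean 0 and population
#' (n-denominator) standard deviation 1 within every dataset. A constant
#' channel maps to all zeros. The per-dataset means and standard deviations
#' are attached as attribute `"scaling"` so that downstream alignment can
#' impute the standardized value corresponding to 0 RPM.
#'
#' @param features A feature tibble with raw `expression_rpm`, `m5c_rpm`.
#' @return The tibble with `expression_z`, `m5c_z` columns filled and a
#'   `"scaling"` attribute (tibble with `dataset_id, expression_mu,
#'   expression_sigma, m5c_mu, m5c_sigma`).
#' @export
zscore_by_dataset <- function(features) {
  stopifnot(is.data.frame(features))
  sizes <- table(features$dataset_id)
  if (any(sizes < 2L)) {
    abort(sprintf("Dataset %s has fewer than 2 genes; cannot standardize.",
                  names(sizes)[which(sizes < 2L)[1]]))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  scaling <- features |>
    group_by(.data$dataset_id) |>
    summarise(expression_mu = mean(.data$expression_rpm),
              expression_sigma = pop_sd(.data$expression_rpm),
              m5c_mu = mean(.data$m5c_rpm),
              m5c_sigma = pop_sd(.data$m5c_rpm),
              .groups = "drop")
  zcol <- function(x, mu, sigma) ifelse(sigma > 0, (x - mu) / pmax(sigma, 1e-300), 0)
  out <- features |>
    left_join(scaling, by = "dataset_id") |>
    mutate(expression_z = zcol(.data$expression_rpm, .data$expression_mu,
                               .data$expression_sigma),
           m5c_z = zcol(.data$m5c_rpm, .data$m5c_mu, .data$m5c_sigma)) |>
    select(-"expression_mu", -"expression_sigma", -"m5c_mu", -"m5c_sigma")
  attr(out, "scaling") <- scaling
  out
}

#' Filter differential m5C peaks
#'
#' Keeps peaks with \eqn{|log2 FC| \ge log2(fc\_threshold)} and
#' \eqn{p < p\_threshold}, the standard differential-peak criterion
#' (1.5-fold change and p < 0.05 by default), and counts up-regulated
#' (`log2_fc > 0`) and down-regulated (`log2_fc < 0`) survivors.
#'
#' @param peaks Peak records; `log2_fc` and `p_value` must be present and
#'   non-missing on every row.
#' @param fc_threshold Fold-change threshold on the linear scale (1.5).
#' @param p_threshold P-value cutoff (0.05, strict inequality).
#' @return The retained peak tibble with attributes `n_up` and `n_down`.
#' @export
filter_differential_peaks <- function(peaks, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(is.data.frame(peaks))
  if (!all(c("log2_fc", "p_value") %in% names(peaks)) ||
      anyNA(peaks$log2_fc) || anyNA(peaks$p_value)) {
    abort("filter_differential_peaks() needs complete `log2_fc` and `p_value` columns.")
  }
  keep <- abs(peaks$log2_fc) >= log2(fc_threshold) & peaks$p_value < p_threshold
  out <- peaks[keep, , drop = FALSE]
  attr(out, "n_up") <- sum(out$log2_fc > 0)
  attr(out, "n_down") <- sum(out$log2_fc < 0)
  out
}
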