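#' Tidy the training history of a fitted model
#'
#' @param x A `gat_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch and loss type: `epoch, split,
#'   loss`.
#' @method tidy gat_fit
#' @export
tidy.gat_fit <- function(x, ...) {
  x$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"), names_to = "split",
                        values_to = "loss") |>
    mutate(split = ifelse(.data$split == "train_loss", "train", "validation"))
}

#' One-row summary of a fitted model
#'
#' @param x A `gat_fit`.
#' @param ... Unused.
#' @return A tibble with `n_genes, n_parameters, epochs_run, best_epoch,
#'   best_val_loss, final_train_loss`.
#' @method glance gat_fit
#' @export
glance.gat_fit <- function(x, ...) {
  tibble(
    n_genes = length(x$net_nodes),
    n_parameters = sum(trainable_mask(x$params)),
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$history$val_loss[x$best_epoch],
    final_train_loss = x$history$train_loss[x$stopped_epoch]
  )
}

#' Plot training and validation loss curves
#'
#' @param object A `gat_fit`.
#' @param ... Unused.
#' @return A ggplot object; the best epoch is marked with a vertical line.
#' @importFrom ggplot2 autoplot
#' @method autoplot gat_fit
#' @export
autoplot.gat_fit <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    geom_line() +
    geom_vline(xintercept = object$best_epoch, linetype = "dashed",
               colour = "grey40") +
    labs(x = "Epoch", y = "Binary cross-entropy", colour = NULL,
         title = "Training trajectory",
         subtitle = sprintf("Best validation loss at epoch %d", object$best_epoch)) +
    theme_minimal()
}

#' Plot the score distribution of a score table
#'
#' @param scores A score tibble from [score_genes()].
#' @param truth Optional character vector of ground-truth genes; when
#'   given, distributions are overlaid by truth status.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, truth = NULL) {
  df <- scores
  if (is.null(truth)) {
    ggplot(df, aes(x = .data$raw_score)) +
      geom_histogram(bins = 40, fill = "steelblue") +
      labs(x = "Raw importance score", y = "Genes") +
      theme_minimal()
  } else {
    df$status <- ifelse(df$gene_id %in% clean_symbols(truth),
                        "functional", "other")
    ggplot(df, aes(x = .data$raw_score, fill = .data$status)) +
      geom_density(alpha = 0.5) +
      labs(x = "Raw importance score", y = "Density", fill = NULL) +
      theme_minimal()
  }
}

#' Plot the degree distribution of a PPI network
#'
#' @param net A `ppi_network`.
#' @return A ggplot object on log-log axes.
#' @export
plot_degree_distribution <- function(net) {
  tibble(degree = as.integer(net$degree)) |>
    count(.data$degree) |>
    filter(.data$degree > 0) |>
    ggplot(aes(x = .data$degree, y = .data$n)) +
    geom_point() +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "Degree", y = "Genes") +
    theme_minimal()
}
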