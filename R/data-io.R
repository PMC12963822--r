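#' Read a protein-protein interaction edge list
#'
#' Parses a two- or three-column interaction table into a tibble of edge
#' records. Gene identifiers are whitespace-stripped and upper-cased;
#' self-interactions are dropped with a warning (structural self-loops are
#' added later, explicitly, by the attention layers). Duplicate lines are
#' returned as-is: deduplication across sources is [build_network()]'s job.
#'
#' @param path Path to the edge-list file. For `format = "tsv"` this is a
#'   whitespace/tab-delimited file with two gene-symbol columns and an
#'   optional third source-database column; lines starting with `#` are
#'   skipped. For `format = "biogrid-tab"` a tab-delimited export with a
#'   header naming `Official Symbol Interactor A` / `B` columns.
#' @param format One of `"tsv"` (default) or `"biogrid-tab"`.
#'
#' @return A tibble with columns `gene_a`, `gene_b`, `source`, one row per
#'   retained interaction line, with attribute `n_self_dropped` counting
#'   removed self-interactions.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\tdb1", "B\tC\tdb1"), f)
#' read_edge_list(f)
read_edge_list <- function(path, format = c("tsv", "biogrid-tab")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("Edge-list file does not exist: %s", path))

  if (format == "biogrid-tab") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                           name_repair = "minimal")
    cols <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    if (!all(cols %in% names(tab))) {
      abort(sprintf("biogrid-tab file must contain columns: %s",
                    paste(cols, collapse = ", ")))
    }
    rec <- tibble(gene_a = clean_symbols(tab[[cols[1]]]),
                  gene_b = clean_symbols(tab[[cols[2]]]),
                  source = "BioGRID")
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (length(idx) == 0L) abort(sprintf("Edge-list file is empty: %s", path))
    fields <- strsplit(trimws(lines[idx]), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      abort(sprintf("Malformed edge-list line %d in %s: need at least 2 fields.",
                    idx[which(nf < 2L)[1]], path))
    }
    rec <- tibble(
      gene_a = clean_symbols(vapply(fields, `[[`, "", 1L)),
      gene_b = clean_symbols(vapply(fields, `[[`, "", 2L)),
      source = ifelse(nf >= 3L, vapply(fields, function(x) trimws(x[3]), ""), "ppi")
    )
  }

  self <- rec$gene_a == rec$gene_b
  if (any(self)) {
    warn(sprintf("Dropped %d self-interaction(s) from %s.", sum(self), path))
    rec <- rec[!self, , drop = FALSE]
  }
  if (nrow(rec) == 0L) abort(sprintf("No usable interactions in %s.", path))
  attr(rec, "n_self_dropped") <- sum(self)
  rec
}

peak_schema <- c("chrom", "start", "end", "strand", "gene_id", "m5c_rpm")

validate_peaks <- function(peaks, where) {
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad)) {
    abort(sprintf("%s: row %d has start >= end (coordinates are 0-based half-open).",
                  where, bad[1]))
  }
  bad <- which(peaks$m5c_rpm < 0)
  if (length(bad)) abort(sprintf("%s: row %d has negative m5c_rpm.", where, bad[1]))
  bad <- which(!peaks$strand %in% c("+", "-", "."))
  if (length(bad)) abort(sprintf("%s: row %d has strand outside {+,-,.}.", where, bad[1]))
  if ("p_value" %in% names(peaks)) {
    pv <- peaks$p_value
    bad <- which(!is.na(pv) & (pv < 0 | pv > 1))
    if (length(bad)) abort(sprintf("%s: row %d has p_value outside [0, 1].", where, bad[1]))
  }
  invisible(peaks)
}

#' Read MeRIP-seq peak and expression quantification tables
#'
#' Reads the per-peak m5C quantification and the per-gene expression table
#' for one MeRIP-seq dataset, attaching `dataset_id` to every record. Peaks
#' use BED-style 0-based half-open coordinates.
#'
#' Two peak layouts are accepted: a header-bearing TSV with named columns
#' `chrom, start, end, strand, gene_id, m5c_rpm` (optional `log2_fc`,
#' `p_value`), or headerless BED6+3 (`chrom, start, end, name = gene_id,
#' score = m5c_rpm, strand, log2_fc, p_value, dataset_id`). The expression
#' table is a TSV with named columns `gene_id, expression_rpm`, or the same
#' two columns headerless.
#'
#' @param peaks_path,expression_path Paths to the two tables.
#' @param dataset_id Label of the originating MeRIP-seq dataset.
#'
#' @return A list with tibbles `peaks` and `expression`. Rows violating the
#'   record invariants (`start < end`, non-negative RPM, p-values in
#'   \eqn{[0,1]}) raise an error naming the offending row.
#' @export
read_quantification <- function(peaks_path, expression_path, dataset_id) {
  if (!file.exists(peaks_path)) abort(sprintf("Peak table does not exist: %s", peaks_path))
  if (!file.exists(expression_path)) {
    abort(sprintf("Expression table does not exist: %s", expression_path))
  }
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L)

  first <- readLines(peaks_path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  if (has_header) {
    peaks <- readr::read_tsv(peaks_path, show_col_types = FALSE, progress = FALSE,
                             comment = "#")
    missing <- setdiff(peak_schema, names(peaks))
    if (length(missing)) {
      abort(sprintf(
        "Peak table %s is missing required column(s) %s; expected schema: %s [, log2_fc, p_value].",
        peaks_path, paste(missing, collapse = ", "), paste(peak_schema, collapse = ", ")))
    }
  } else {
    peaks <- readr::read_tsv(peaks_path, show_col_types = FALSE, progress = FALSE,
                             comment = "#", col_names = FALSE)
    if (ncol(peaks) < 6L) {
      abort(sprintf("Headerless peak table %s must be BED6+3 (>= 6 columns).", peaks_path))
    }
    bed_names <- c("chrom", "start", "end", "gene_id", "m5c_rpm", "strand",
                   "log2_fc", "p_value", "dataset_id")
    names(peaks)[seq_len(min(ncol(peaks), 9L))] <- bed_names[seq_len(min(ncol(peaks), 9L))]
  }

  for (col in c("start", "end", "m5c_rpm")) {
    v <- suppressWarnings(as.numeric(peaks[[col]]))
    bad <- which(is.na(v) & !is.na(peaks[[col]]))
    if (length(bad)) {
      abort(sprintf("Peak table %s: row %d has non-numeric `%s`.", peaks_path, bad[1], col))
    }
    peaks[[col]] <- v
  }
  peaks <- peaks |>
    mutate(gene_id = clean_symbols(.data$gene_id),
           strand = as.character(.data$strand),
           dataset_id = .env$dataset_id)
  validate_peaks(peaks, peaks_path)

  first <- readLines(expression_path, n = 1L)
  if (grepl("gene_id", first, fixed = TRUE)) {
    expr <- readr::read_tsv(expression_path, show_col_types = FALSE, progress = FALSE,
                            comment = "#")
    if (!all(c("gene_id", "expression_rpm") %in% names(expr))) {
      abort(sprintf("Expression table %s needs columns gene_id, expression_rpm.",
                    expression_path))
    }
  } else {
    expr <- readr::read_tsv(expression_path, show_col_types = FALSE, progress = FALSE,
                            comment = "#", col_names = c("gene_id", "expression_rpm"))
  }
  expr$expression_rpm <- suppressWarnings(as.numeric(expr$expression_rpm))
  bad <- which(is.na(expr$expression_rpm))
  if (length(bad)) {
    abort(sprintf("Expression table %s: row %d has non-numeric expression_rpm.",
                  expression_path, bad[1]))
  }
  if (any(expr$expression_rpm < 0)) {
    abort(sprintf("Expression table %s contains negative expression_rpm.", expression_path))
  }
  expr <- expr |>
    mutate(gene_id = clean_symbols(.data$gene_id), dataset_id = .env$dataset_id) |>
    select("gene_id", "expression_rpm", "dataset_id")

  list(peaks = as_tibble(peaks), expression = as_tibble(expr))
}

#' Write and read a gene score table
#'
#' The on-disk format is a TSV with columns `gene_id, raw_score,
#' minmax_score, z_score, rank`, rows sorted by descending raw score with
#' lexicographic gene-id tie-break, numeric columns printed with six decimal
#' places and 1-based ranks.
#'
#' @param scores A score table as returned by [score_genes()] (any data
#'   frame with the four score columns).
#' @param path Output path.
#' @return `write_score_table()` returns `path` invisibly;
#'   `read_score_table()` returns the score tibble.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(is.data.frame(scores))
  if (nrow(scores) == 0L) abort("Refusing to write an empty score table.")
  need <- c("gene_id", "raw_score", "minmax_score", "z_score")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    abort(sprintf("Score table is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  out <- scores |>
    arrange(desc(.data$raw_score), .data$gene_id) |>
    mutate(rank = seq_len(n())) |>
    select("gene_id", "raw_score", "minmax_score", "z_score", "rank") |>
    mutate(across(c("raw_score", "minmax_score", "z_score"), ~ sprintf("%.6f", .x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Score table does not exist: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    mutate(gene_id = clean_symbols(.data$gene_id))
}

#' Read a ground-truth gene list
#'
#' One gene symbol per line; `#` comments and blank lines are skipped;
#' symbols are upper-cased and deduplicated.
#'
#' @param path Path to the list file.
#' @return A character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("Gene list does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- unique(clean_symbols(lines[nzchar(trimws(lines))]))
  if (length(genes) == 0L) abort(sprintf("Gene list %s contains no symbols.", path))
  genes
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a tab-delimited GMT file (set name, description, then
#'   member genes).
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file does not exist: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) abort(sprintf("GMT line %d has fewer than 3 fields.", bad[1]))
  sets <- lapply(fields, function(x) unique(clean_symbols(x[-c(1, 2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Read or write a flat run configuration
#'
#' A YAML key-value file mirroring the fields of [gat_config()],
#' [train_config()] and the RWR/benchmark options; unknown keys are kept so
#' callers can round-trip their own settings.
#'
#' @param path Path to the YAML file.
#' @param config A named list.
#' @return `read_run_config()` returns a named list; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file does not exist: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path)
  invisible(path)
}
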