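# Tab-delimited I/O.  All formats are plain text: count matrices with a
# `gene` id column and optional `class` column, allelic tables with one row
# per (gene, sample), size factors as two-column TSVs, and reports as JSON.
# Writing then reading reproduces integer matrices exactly and real-valued
# matrices to full double precision.

.parse_error <- function(msg, path = NULL, line = NULL) {
  loc <- if (!is.null(line)) sprintf(" at line %d", line) else ""
  full <- sprintf("parse error%s%s: %s",
                  if (!is.null(path)) paste0(" in ", path) else "", loc, msg)
  stop(structure(class = c("osncistrans_parse_error", "error", "condition"),
                 list(message = full, call = sys.call(-1))))
}

#' Write a count matrix as tab-delimited text
#'
#' Columns: `gene`, `class`, then one column per sample.  Real values are
#' written with 17 significant digits so the round trip is exact to double
#' precision.
#'
#' @param x A `count_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  vals <- if (x$normalized) {
    apply(x$counts, 2L, function(col) sprintf("%.17g", col))
  } else {
    apply(x$counts, 2L, function(col) sprintf("%d", as.integer(col)))
  }
  df <- data.frame(gene = rownames(x$counts),
                   class = as.character(x$gene_class), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene", "class", colnames(x$counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from tab-delimited text
#'
#' Expects a header with `gene`, optionally `class`, then sample columns.
#' Ragged rows, duplicate gene/sample ids and negative counts are rejected
#' with the offending line number.
#'
#' @param path Input file path.
#' @param normalized Logical; read values as real-valued normalized data.
#' @param sample_meta Optional path to a sample metadata TSV with a
#'   `sample` column.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(path, normalized = FALSE, sample_meta = NULL) {
  if (!file.exists(path)) .parse_error("file does not exist", path)
  if (file.size(path) == 0L) .parse_error("empty input file", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(fields) < 2L) .parse_error("no data rows", path)
  ragged <- which(fields != fields[1L])
  if (length(ragged)) {
    .parse_error(sprintf("ragged row (%d fields, expected %d)",
                         fields[ragged[1L]], fields[1L]),
                 path, line = ragged[1L])
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) .parse_error("missing `gene` column", path)
  has_class <- "class" %in% names(df)
  sample_cols <- setdiff(names(df), c("gene", "class"))
  if (!length(sample_cols)) .parse_error("no sample columns", path)
  dup <- which(duplicated(df$gene))
  if (length(dup)) {
    .parse_error(paste0("duplicate gene id '", df$gene[dup[1L]], "'"),
                 path, line = dup[1L] + 1L)
  }
  if (anyDuplicated(sample_cols)) .parse_error("duplicate sample ids", path)
  mat <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(df[, sample_cols, drop = FALSE], 1L,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    .parse_error("non-numeric count",
                 path, line = if (length(bad)) bad[1L] + 1L else NULL)
    }
  neg <- which(apply(mat, 1L, function(r) any(r < 0)))
  if (length(neg)) .parse_error("negative count", path, line = neg[1L] + 1L)
  rownames(mat) <- df$gene
  count_matrix(mat,
               gene_class = if (has_class) df$class else NULL,
               sample_meta = if (!is.null(sample_meta)) {
                 utils::read.delim(sample_meta, stringsAsFactors = FALSE)
               },
               normalized = normalized)
}

#' Write an allelic count table as tab-delimited text
#' @param x An `allelic_count_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_allelic_table <- function(x, path) {
  stopifnot(inherits(x, "allelic_count_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an allelic count table from tab-delimited text
#' @param path Input file path.
#' @param allele_labels Labels for allele 1 and allele 2.
#' @return An `allelic_count_table`.
#' @export
read_allelic_table <- function(path, allele_labels = c("B6", "CAST")) {
  if (!file.exists(path)) .parse_error("file does not exist", path)
  if (file.size(path) == 0L) .parse_error("empty input file", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample", "allele1_count", "allele2_count")
  if (!all(need %in% names(df))) {
    .parse_error(paste("missing column(s):",
                       paste(setdiff(need, names(df)), collapse = ", ")), path)
  }
  for (col in c("allele1_count", "allele2_count")) {
    neg <- which(df[[col]] < 0)
    if (length(neg)) .parse_error("negative count", path, line = neg[1L] + 1L)
  }
  allelic_count_table(df, allele_labels = allele_labels)
}

#' Write size factors as a two-column TSV (sample, factor)
#' @param s A `size_factors` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_size_factors <- function(s, path) {
  stopifnot(inherits(s, "size_factors"))
  utils::write.table(
    data.frame(sample = names(s), factor = sprintf("%.17g", as.numeric(s))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read size factors from a two-column TSV
#' @param path Input file path.
#' @param kind `"depth"` or `"osn_content"`.
#' @return A `size_factors` object.
#' @export
read_size_factors <- function(path, kind = c("depth", "osn_content")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "factor") %in% names(df))) {
    .parse_error("expected columns `sample` and `factor`", path)
  }
  size_factors(stats::setNames(as.numeric(df$factor), df$sample), kind = kind)
}

#' Write a cis/trans report as JSON (summary) and TSV (per-gene table)
#'
#' @param report A `cistrans_report` from [run_cistrans()].
#' @param path JSON output path; the per-gene fold-change table is written
#'   next to it with suffix `_genes.tsv` unless `gene_table_path` is given.
#' @param gene_table_path Optional explicit path for the per-gene TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, gene_table_path = NULL) {
  stopifnot(inherits(report, "cistrans_report"))
  if (is.null(gene_table_path)) {
    gene_table_path <- sub("\\.json$", "", path)
    gene_table_path <- paste0(gene_table_path, "_genes.tsv")
  }
  summary <- report[setdiff(names(report),
                            c("fc_table", "deviation", "gate",
                              "depth_factors", "osn_factors"))]
  summary$kept_markers <- report$gate$kept
  summary$marker_correlations <- as.list(round(report$gate$correlations, 6))
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tab <- report$fc_table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  utils::write.table(tab, gene_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
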