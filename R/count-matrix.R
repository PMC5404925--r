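# Core containers: the gene-by-sample count matrix (with gene classes and
# sample metadata) and the per-gene/per-sample allelic count table.

GENE_CLASSES <- c("OR", "marker", "other")

#' Construct a gene-by-sample count matrix
#'
#' The universal currency of the pipeline: a numeric matrix of non-negative
#' counts with unique gene and sample identifiers, a per-gene class
#' (`"OR"`, `"marker"` or `"other"`) driving which rows are normalized for
#' OSN content, and optional per-sample metadata.
#'
#' @param counts Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.  Must be non-negative; integer-valued unless
#'   `normalized = TRUE`.
#' @param gene_class Character vector of gene classes, one per row (recycled
#'   if length 1).  Defaults to `"OR"` for every gene.
#' @param sample_meta Optional `data.frame` with one row per sample (matched
#'   by a `sample` column or by row names), e.g. strain/sex/condition.
#' @param normalized Logical; `TRUE` marks a real-valued (normalized) matrix,
#'   relaxing the integer constraint.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_class = NULL, sample_meta = NULL,
                         normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  if (!normalized && any(counts != round(counts))) {
    stop("raw counts must be integer-valued (use normalized = TRUE for real values)")
  }
  storage.mode(counts) <- "double"
  if (is.null(gene_class)) gene_class <- "OR"
  if (length(gene_class) == 1L) gene_class <- rep(gene_class, nrow(counts))
  if (length(gene_class) != nrow(counts)) {
    stop("`gene_class` must have one entry per gene")
  }
  if (!all(gene_class %in% GENE_CLASSES)) {
    stop("gene classes must be one of: ", paste(GENE_CLASSES, collapse = ", "))
  }
  names(gene_class) <- rownames(counts)
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if ("sample" %in% names(sample_meta)) {
      rownames(sample_meta) <- sample_meta$sample
    }
    missing <- setdiff(colnames(counts), rownames(sample_meta))
    if (length(missing)) {
      stop("sample_meta missing samples: ", paste(missing, collapse = ", "))
    }
    sample_meta <- sample_meta[colnames(counts), , drop = FALSE]
  }
  structure(
    list(counts = counts, gene_class = gene_class, sample_meta = sample_meta,
         normalized = normalized),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$normalized) "normalized" else "raw counts"))
  tab <- table(x$gene_class)
  cat("  gene classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  samples:", paste(utils::head(colnames(x$counts), 6L), collapse = ", "),
      if (ncol(x$counts) > 6L) "..." else "", "\n")
  invisible(x)
}

#' Gene ids of a given class
#' @param x A `count_matrix`.
#' @param class One of `"OR"`, `"marker"`, `"other"`.
#' @return Character vector of gene ids.
#' @export
genes_of_class <- function(x, class) {
  stopifnot(inherits(x, "count_matrix"), class %in% GENE_CLASSES)
  names(x$gene_class)[x$gene_class == class]
}

#' Combine count matrices sample-wise
#'
#' All matrices must share the same genes (same order) and gene classes;
#' sample ids must be globally unique.  Used to normalize parental and F1
#' samples jointly on a common scale.
#'
#' @param ... `count_matrix` objects.
#' @return A `count_matrix` with the union of samples.
#' @export
combine_samples <- function(...) {
  mats <- list(...)
  stopifnot(length(mats) >= 1L, all(vapply(mats, inherits, TRUE, "count_matrix")))
  ref <- mats[[1L]]
  for (m in mats[-1L]) {
    if (!identical(rownames(m$counts), rownames(ref$counts))) {
      stop("count matrices must share the same genes in the same order")
    }
    if (!identical(unname(m$gene_class), unname(ref$gene_class))) {
      stop("count matrices must share gene classes")
    }
  }
  counts <- do.call(cbind, lapply(mats, function(m) m$counts))
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids across matrices")
  metas <- lapply(mats, function(m) m$sample_meta)
  meta <- if (all(vapply(metas, is.null, TRUE))) NULL else {
    filled <- lapply(seq_along(mats), function(i) {
      mi <- metas[[i]]
      if (is.null(mi)) {
        data.frame(sample = colnames(mats[[i]]$counts),
                   row.names = colnames(mats[[i]]$counts))
      } else {
        mi$sample <- rownames(mi)
        mi
      }
    })
    cols <- unique(unlist(lapply(filled, names)))
    filled <- lapply(filled, function(d) {
      for (cn in setdiff(cols, names(d))) d[[cn]] <- NA
      d[, cols, drop = FALSE]
    })
    do.call(rbind, filled)
  }
  count_matrix(counts, gene_class = ref$gene_class, sample_meta = meta,
               normalized = any(vapply(mats, function(m) m$normalized, TRUE)))
}

#' Construct a per-gene, per-sample allelic count table
#'
#' Holds SNP-informative read counts for the two parental alleles of each
#' gene in each F1 sample.  Inputs are assumed pre-filtered upstream: reads
#' that splice across the discriminating SNP or that are not uniquely mapped
#' must already have been excluded.
#'
#' @param table `data.frame` with columns `gene`, `sample`, `allele1_count`,
#'   `allele2_count` (non-negative integers; `(gene, sample)` unique).
#' @param allele_labels Character vector of length 2 naming allele 1 and
#'   allele 2 (default `c("B6", "CAST")`).
#' @return A `data.frame` of class `allelic_count_table`.
#' @export
allelic_count_table <- function(table, allele_labels = c("B6", "CAST")) {
  table <- as.data.frame(table)
  need <- c("gene", "sample", "allele1_count", "allele2_count")
  if (!all(need %in% names(table))) {
    stop("allelic table needs columns: ", paste(need, collapse = ", "))
  }
  cnt <- as.matrix(table[, c("allele1_count", "allele2_count")])
  if (any(!is.finite(cnt)) || any(cnt < 0)) stop("allelic counts must be non-negative")
  if (anyDuplicated(table[, c("gene", "sample")])) {
    stop("duplicate (gene, sample) pairs in allelic table")
  }
  stopifnot(length(allele_labels) == 2L)
  structure(table[, need], allele_labels = allele_labels,
            class = c("allelic_count_table", "data.frame"))
}

#' Per-sample size factors
#'
#' Positive scalars making samples comparable: sequencing-depth factors
#' divide counts, OSN-content factors multiply OR counts.
#'
#' @param values Named positive numeric vector (names are sample ids).
#' @param kind `"depth"` or `"osn_content"`.
#' @return A named numeric vector of class `size_factors`.
#' @export
size_factors <- function(values, kind = c("depth", "osn_content")) {
  kind <- match.arg(kind)
  if (is.null(names(values)) || anyDuplicated(names(values))) {
    stop("size factors must have unique sample names")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("size factors must be positive and finite")
  }
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), kind = kind, class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("size_factors (%s):\n", attr(x, "kind")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
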