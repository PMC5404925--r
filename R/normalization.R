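# Two-stage normalization of OR count matrices: sequencing depth via the
# median-of-ratios estimator, then OSN content via mature-OSN marker genes
# (Omp, Adcy3, Ano2, Cnga2, Gnal).  OR transcript abundance proxies OSN
# subtype counts only after both stages: depth factors make libraries
# comparable, and marker-derived factors rescale OR counts to a common
# amount of OSN-derived RNA per sample.

#' Median-of-ratios sequencing-depth size factors
#'
#' For each gene present in every sample, a pseudo-reference is the
#' geometric mean of its counts across samples; the size factor of sample
#' `j` is the median over those genes of `count_gj / reference_g`, rescaled
#' so the factors have geometric mean one (which makes the estimator
#' exactly idempotent).  Dividing column `j` by `s_j` yields the
#' depth-normalized matrix.
#'
#' @param x A `count_matrix`.
#' @return `size_factors` of kind `"depth"`.
#' @export
depth_size_factors <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  log_ref <- rowMeans(log(counts))
  usable <- is.finite(log_ref)  # finite geometric mean <=> nonzero in every sample
  if (!any(usable)) {
    stop("degenerate input: no gene has nonzero counts in every sample")
  }
  log_ratios <- log(counts[usable, , drop = FALSE]) - log_ref[usable]
  log_s <- apply(log_ratios, 2L, stats::median)
  # rescale to geometric mean 1: the estimator is then exactly idempotent
  s <- exp(log_s - mean(log_s))
  size_factors(stats::setNames(s, colnames(counts)), kind = "depth")
}

#' Divide a count matrix by depth size factors
#'
#' @param x A `count_matrix`.
#' @param s `size_factors` of kind `"depth"` covering all samples of `x`.
#' @return A normalized (real-valued) `count_matrix`.
#' @export
apply_depth_normalization <- function(x, s) {
  stopifnot(inherits(x, "count_matrix"), inherits(s, "size_factors"))
  missing <- setdiff(colnames(x$counts), names(s))
  if (length(missing)) stop("size factors missing samples: ",
                            paste(missing, collapse = ", "))
  norm <- sweep(x$counts, 2L, as.numeric(s[colnames(x$counts)]), "/")
  count_matrix(norm, gene_class = x$gene_class, sample_meta = x$sample_meta,
               normalized = TRUE)
}

#' Gate marker genes on their correlation with total OR counts
#'
#' A marker gene is usable for OSN-content normalization only if its
#' (depth-normalized) expression tracks the per-sample total of OR-class
#' counts.  Markers with rank correlation (average ranks for ties) at or
#' above `threshold` are kept; constant markers are excluded with a
#' warning.
#'
#' @param normalized A depth-normalized `count_matrix`.
#' @param markers Marker gene ids; defaults to the matrix's `"marker"` rows.
#' @param threshold Minimum correlation (default 0.7).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return An object of class `marker_gate` with per-marker correlations,
#'   the kept set and the threshold.
#' @export
marker_gate <- function(normalized, markers = NULL, threshold = 0.7,
                        method = c("spearman", "pearson")) {
  stopifnot(inherits(normalized, "count_matrix"))
  method <- match.arg(method)
  if (is.null(markers)) markers <- genes_of_class(normalized, "marker")
  missing <- setdiff(markers, rownames(normalized$counts))
  if (length(missing)) stop("markers absent from matrix: ",
                            paste(missing, collapse = ", "))
  if (ncol(normalized$counts) < 3L) stop("marker gating needs >= 3 samples")
  or_total <- colSums(normalized$counts[normalized$gene_class == "OR", ,
                                        drop = FALSE])
  cors <- stats::setNames(rep(NA_real_, length(markers)), markers)
  for (m in markers) {
    expr <- normalized$counts[m, ]
    if (stats::sd(expr) == 0 || stats::sd(or_total) == 0) {
      warning("marker '", m, "' excluded: zero variance, correlation undefined")
      next
    }
    cors[m] <- stats::cor(expr, or_total, method = method)
  }
  kept <- names(cors)[!is.na(cors) & cors >= threshold]
  if (!length(kept)) {
    stop("marker gate failure: no marker reaches correlation >= ", threshold)
  }
  structure(list(correlations = cors, kept = kept, threshold = threshold,
                 method = method),
            class = "marker_gate")
}

#' @export
print.marker_gate <- function(x, ...) {
  cat(sprintf("marker_gate (%s, threshold %.2f): kept %d/%d\n",
              x$method, x$threshold, length(x$kept), length(x$correlations)))
  print(round(x$correlations, 3))
  invisible(x)
}

#' OSN-content size factors from gated marker genes
#'
#' The geometric mean `g_j` of the kept markers' normalized values is
#' computed per sample; the factor is `f_j = mean_j(g_j) / g_j`.
#' Multiplying OR counts by `f_j` rescales every sample to the average
#' OSN content.
#'
#' @param normalized A depth-normalized `count_matrix`.
#' @param kept_markers Non-empty set of marker gene ids, all nonzero in
#'   every sample (marker genes are by definition abundantly expressed;
#'   a zero is treated as a data defect, not smoothed over).
#' @param pseudocount Optional value added to marker counts before the
#'   geometric mean, for robustness on sparse data (default 0: hard error
#'   on zeros).
#' @return `size_factors` of kind `"osn_content"`.
#' @export
osn_size_factors <- function(normalized, kept_markers, pseudocount = 0) {
  stopifnot(inherits(normalized, "count_matrix"), length(kept_markers) >= 1L)
  missing <- setdiff(kept_markers, rownames(normalized$counts))
  if (length(missing)) stop("markers absent from matrix: ",
                            paste(missing, collapse = ", "))
  vals <- normalized$counts[kept_markers, , drop = FALSE] + pseudocount
  zero_sample <- colnames(vals)[apply(vals, 2L, function(v) any(v <= 0))]
  if (length(zero_sample)) {
    stop("degenerate input: zero marker value in sample(s): ",
         paste(zero_sample, collapse = ", "))
  }
  g <- exp(colMeans(log(vals)))
  size_factors(stats::setNames(mean(g) / g, colnames(vals)),
               kind = "osn_content")
}

#' Apply OSN-content normalization to the OR rows
#'
#' OR-class rows of sample `j` are multiplied by `f_j`; marker and other
#' rows are left untouched.
#'
#' @param normalized A depth-normalized `count_matrix`.
#' @param f `size_factors` of kind `"osn_content"` covering all samples.
#' @return A `count_matrix` with doubly-normalized OR rows.
#' @export
apply_osn_normalization <- function(normalized, f) {
  stopifnot(inherits(normalized, "count_matrix"), inherits(f, "size_factors"))
  missing <- setdiff(colnames(normalized$counts), names(f))
  if (length(missing)) stop("size factors missing samples: ",
                            paste(missing, collapse = ", "))
  out <- normalized$counts
  or_rows <- normalized$gene_class == "OR"
  out[or_rows, ] <- sweep(out[or_rows, , drop = FALSE], 2L,
                          as.numeric(f[colnames(out)]), "*")
  count_matrix(out, gene_class = normalized$gene_class,
               sample_meta = normalized$sample_meta, normalized = TRUE)
}

#' Full two-stage normalization
#'
#' Convenience wrapper: depth size factors, marker gate, OSN-content
#' factors, and OR-row rescaling in one call.
#'
#' @param x A raw `count_matrix` containing OR and marker rows.
#' @param markers Marker ids (default: the matrix's `"marker"` rows).
#' @param threshold Marker-gate correlation threshold.
#' @param method Correlation flavor for the gate.
#' @return List with `normalized` (doubly-normalized matrix),
#'   `depth_factors`, `osn_factors` and `gate`.
#' @export
normalize_two_stage <- function(x, markers = NULL, threshold = 0.7,
                                method = c("spearman", "pearson")) {
  s <- depth_size_factors(x)
  depth_norm <- apply_depth_normalization(x, s)
  gate <- marker_gate(depth_norm, markers = markers, threshold = threshold,
                      method = method)
  f <- osn_size_factors(depth_norm, gate$kept)
  list(normalized = apply_osn_normalization(depth_norm, f),
       depth_factors = s, osn_factors = f, gate = gate)
}
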