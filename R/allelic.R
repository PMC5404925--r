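# Allele-specific expression: the informative-count filter, per-gene allelic
# ratios from SNP-informative counts, and deconvolution of total expression
# into allele-specific values.

# Per-sample weight turning raw SNP counts into (doubly) normalized values:
# divide by the depth factor, multiply by the OSN-content factor.
.allelic_weights <- function(samples, depth_factors, osn_factors) {
  w <- rep(1, length(samples))
  names(w) <- samples
  if (!is.null(depth_factors)) {
    missing <- setdiff(samples, names(depth_factors))
    if (length(missing)) stop("depth factors missing samples: ",
                              paste(missing, collapse = ", "))
    w <- w / as.numeric(depth_factors[samples])
  }
  if (!is.null(osn_factors)) {
    missing <- setdiff(samples, names(osn_factors))
    if (length(missing)) stop("OSN factors missing samples: ",
                              paste(missing, collapse = ", "))
    w <- w * as.numeric(osn_factors[samples])
  }
  w
}

#' Filter genes on normalized SNP-informative counts
#'
#' Per gene, the total normalized informative counts (both alleles, all
#' samples, after depth and OSN-content normalization) are computed; genes
#' strictly above the first quartile of this distribution are kept.  The
#' quartile uses linear interpolation between order statistics.
#'
#' @param allelic An `allelic_count_table`.
#' @param depth_factors Optional `size_factors` (kind `"depth"`) covering
#'   all samples in the table.
#' @param osn_factors Optional `size_factors` (kind `"osn_content"`).
#' @param quartile Quantile defining the cutoff (default 0.25).
#' @return Character vector of kept gene ids, with attributes `totals`
#'   (the normalized per-gene totals) and `threshold`.
#' @export
informative_gene_filter <- function(allelic, depth_factors = NULL,
                                    osn_factors = NULL, quartile = 0.25) {
  stopifnot(inherits(allelic, "allelic_count_table"))
  if (nrow(allelic) == 0L) stop("empty allelic table")
  w <- .allelic_weights(unique(allelic$sample), depth_factors, osn_factors)
  value <- (allelic$allele1_count + allelic$allele2_count) * w[allelic$sample]
  totals <- tapply(value, allelic$gene, sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  threshold <- stats::quantile(totals, probs = quartile, type = 7, names = FALSE)
  kept <- names(totals)[totals > threshold]
  if (!length(kept)) {
    warning("no gene strictly above the quartile cutoff; all totals may be tied")
  }
  structure(kept, totals = totals, threshold = threshold)
}

#' Per-gene allelic ratios from SNP-informative counts
#'
#' The ratio is the allele-1 share, `r = allele1 / (allele1 + allele2)`.
#' Under the default pooling, counts are summed across samples per gene
#' before the ratio is taken (optionally after per-sample normalization
#' weights); `per_sample` returns one ratio per gene and sample.  Entries
#' with zero informative counts are omitted and reported in the `skipped`
#' attribute.
#'
#' @param allelic An `allelic_count_table`.
#' @param pooling `"pooled"` (default) or `"per_sample"`.
#' @param depth_factors,osn_factors Optional `size_factors` normalizing the
#'   SNP counts before pooling (the same factors used for total expression).
#' @return `data.frame` with columns `gene` (and `sample` under
#'   `per_sample`), `r` and `informative_total` (raw informative counts
#'   backing the estimate); attribute `skipped` lists omitted entries.
#' @export
allelic_ratio <- function(allelic, pooling = c("pooled", "per_sample"),
                          depth_factors = NULL, osn_factors = NULL) {
  stopifnot(inherits(allelic, "allelic_count_table"))
  pooling <- match.arg(pooling)
  w <- .allelic_weights(unique(allelic$sample), depth_factors, osn_factors)
  a1 <- allelic$allele1_count * w[allelic$sample]
  a2 <- allelic$allele2_count * w[allelic$sample]
  if (pooling == "pooled") {
    s1 <- tapply(a1, allelic$gene, sum)
    s2 <- tapply(a2, allelic$gene, sum)
    raw <- tapply(allelic$allele1_count + allelic$allele2_count,
                  allelic$gene, sum)
    genes <- names(s1)
    tot <- as.numeric(s1) + as.numeric(s2)
    keep <- tot > 0
    out <- data.frame(gene = genes[keep],
                      r = as.numeric(s1)[keep] / tot[keep],
                      informative_total = as.numeric(raw)[keep],
                      stringsAsFactors = FALSE)
    skipped <- genes[!keep]
  } else {
    tot <- a1 + a2
    keep <- tot > 0
    out <- data.frame(gene = allelic$gene[keep],
                      sample = allelic$sample[keep],
                      r = a1[keep] / tot[keep],
                      informative_total = allelic$allele1_count[keep] +
                        allelic$allele2_count[keep],
                      stringsAsFactors = FALSE)
    skipped <- unique(allelic$gene[!keep])
  }
  rownames(out) <- NULL
  if (length(skipped)) {
    message(length(skipped), " gene entr",
            if (length(skipped) == 1L) "y" else "ies",
            " skipped for zero informative counts")
  }
  structure(out, skipped = skipped)
}

#' Deconvolve total expression into allele-specific expression
#'
#' The total (doubly-normalized) expression of each gene is split by the
#' allelic ratio: `allele1 = total * r` and `allele2 = total * (1 - r)`,
#' so the two allelic values always sum to the total.
#'
#' @param totals Named numeric vector of total expression per gene, or a
#'   `data.frame` with columns `gene` and `total_value`.
#' @param ratios `data.frame` from [allelic_ratio()] (pooled mode), with
#'   columns `gene` and `r`.
#' @return `data.frame` with columns `gene`, `allele1_value`,
#'   `allele2_value`, `total_value` for genes present in both inputs.
#' @export
deconvolve_alleles <- function(totals, ratios) {
  if (is.numeric(totals)) {
    if (is.null(names(totals))) stop("`totals` must be named by gene")
    totals <- data.frame(gene = names(totals), total_value = as.numeric(totals),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "total_value") %in% names(totals)),
            all(c("gene", "r") %in% names(ratios)))
  if (any(ratios$r < 0 | ratios$r > 1)) {
    stop("allelic ratios must lie in [0, 1]")
  }
  merged <- merge(totals[, c("gene", "total_value")],
                  ratios[, c("gene", "r")], by = "gene", sort = TRUE)
  out <- data.frame(gene = merged$gene,
                    allele1_value = merged$total_value * merged$r,
                    allele2_value = merged$total_value * (1 - merged$r),
                    total_value = merged$total_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
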