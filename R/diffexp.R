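# Lightweight negative-binomial differential-abundance test.  This is a
# deliberately simple method-of-moments Wald test applying the "adjusted
# p <= 0.05" calling rule end-to-end on count data; it uses no dispersion
# shrinkage and makes no attempt to reproduce the gene lists of a full
# empirical-Bayes NB fit.

#' Method-of-moments per-gene dispersion
#'
#' `alpha_g = max(0, (var_g - mean_g) / mean_g^2)`, estimated within each
#' group and pooled across groups with degrees-of-freedom weights.  Genes
#' with zero mean in every group get `NA` and are listed in the `flagged`
#' attribute.
#'
#' @param counts Numeric matrix (genes x samples), normalized or raw.
#' @param groups Factor/character of length `ncol(counts)` with >= 2
#'   replicates per level.
#' @return Named numeric vector of dispersions with attribute `flagged`.
#' @export
estimate_dispersion <- function(counts, groups) {
  stopifnot(is.matrix(counts))
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts)) {
    stop("`groups` must have one entry per sample")
  }
  if (any(table(groups) < 2L)) {
    stop("need at least 2 replicates per group to estimate dispersion")
  }
  num <- den <- rep(0, nrow(counts))
  for (g in levels(groups)) {
    sub <- counts[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    df <- ncol(sub) - 1L
    ok <- m > 0
    num[ok] <- num[ok] + df * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + df
  }
  alpha <- ifelse(den > 0, pmax(0, num / pmax(den, 1)), NA_real_)
  names(alpha) <- rownames(counts)
  structure(alpha, flagged = rownames(counts)[den == 0])
}

#' Negative-binomial Wald test for two groups
#'
#' Per gene, the statistic is the log2 ratio of normalized group means over
#' its delta-method standard error with NB variance
#' `(1/mu + alpha_g)/n` per group, referred to a t distribution with
#' `n_A + n_B - 2` degrees of freedom; p-values are BH-adjusted and genes
#' are called significant at `q <= fdr`.  Genes with zero counts in every
#' sample are excluded and listed in the `excluded` attribute.
#'
#' @param counts Integer matrix (genes x samples) of raw counts.
#' @param groups Factor/character with exactly two levels (the reported
#'   log2 fold change is level 1 vs level 2); >= 2 replicates each.
#' @param size_factors Optional named per-sample `size_factors` (or plain
#'   named vector) to divide counts by; default 1.
#' @param fdr FDR threshold for the `significant` call (default 0.05).
#' @param pseudocount Added to group means before the log ratio
#'   (default 0.5).
#' @return `data.frame` with columns `gene`, `base_mean`, `log2fc`,
#'   `alpha`, `stat`, `p`, `q`, `significant`; attribute `excluded`.
#' @export
nb_wald_test <- function(counts, groups, size_factors = NULL, fdr = 0.05,
                         pseudocount = 0.5) {
  stopifnot(is.matrix(counts))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  if (any(table(groups) < 2L)) stop("need at least 2 replicates per group")
  if (length(groups) != ncol(counts)) {
    stop("`groups` must have one entry per sample")
  }
  norm <- counts
  if (!is.null(size_factors)) {
    missing <- setdiff(colnames(counts), names(size_factors))
    if (length(missing)) stop("size factors missing samples: ",
                              paste(missing, collapse = ", "))
    norm <- sweep(counts, 2L, as.numeric(size_factors[colnames(counts)]), "/")
  }
  nonzero <- rowSums(norm) > 0
  excluded <- rownames(counts)[!nonzero]
  norm <- norm[nonzero, , drop = FALSE]
  alpha <- estimate_dispersion(norm, groups)
  lvl <- levels(groups)
  a <- norm[, groups == lvl[1L], drop = FALSE]
  b <- norm[, groups == lvl[2L], drop = FALSE]
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  log2fc <- log2((m_a + pseudocount) / (m_b + pseudocount))
  # delta-method variance of log2 of an NB group mean
  var_log2 <- function(m, n) (1 / pmax(m, pseudocount) + alpha) / n / log(2)^2
  se <- sqrt(var_log2(m_a, ncol(a)) + var_log2(m_b, ncol(b)))
  stat <- log2fc / se
  df <- ncol(a) + ncol(b) - 2L
  p <- 2 * stats::pt(-abs(stat), df = df)
  q <- bh_adjust(p)
  out <- data.frame(gene = rownames(norm),
                    base_mean = (m_a + m_b) / 2,
                    log2fc = log2fc, alpha = as.numeric(alpha),
                    stat = stat, p = p, q = q,
                    significant = q <= fdr,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, excluded = excluded, fdr = fdr,
            comparison = paste(lvl[1L], "vs", lvl[2L]))
}
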