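# Statistical primitives: Lin's concordance correlation coefficient with its
# bias-correction factor C_b, rank/Pearson correlation, log2 fold changes,
# exact hypergeometric upper tails (log-space, stable down to ~1e-300),
# Benjamini-Hochberg adjustment, and qPCR relative quantity.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with population
#' (1/n) second moments, so that the decomposition `ccc = r * C_b` is exact.
#' `C_b = 2 / (v + 1/v + u^2)` with `v = s_x/s_y` and
#' `u = (mean_x - mean_y)/sqrt(s_x s_y)` quantifies how far the best-fit
#' line deviates from `x = y` (`C_b = 1` means no deviation); `r` is the
#' Pearson correlation.
#'
#' @param x,y Finite numeric vectors of equal length >= 3.
#' @param keep_pairs Keep the `(x, y)` pairs in the result (for plotting).
#' @return An object of class `concordance_report` with elements `ccc`,
#'   `c_b`, `pearson_r`, `n_genes` and optionally `x`, `y`.
#' @export
lin_ccc <- function(x, y, keep_pairs = TRUE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0) stop("undefined statistic: zero variance in x or y")
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  v <- sqrt(sx2 / sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  c_b <- 2 / (v + 1 / v + u^2)
  out <- list(ccc = ccc, c_b = c_b, pearson_r = r, n_genes = n)
  if (keep_pairs) { out$x <- x; out$y <- y }
  structure(out, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: ccc = %.4f, C_b = %.4f, r = %.4f (n = %d)\n",
              x$ccc, x$c_b, x$pearson_r, x$n_genes))
  invisible(x)
}

#' Rank (Spearman) correlation with average ranks for ties
#' @param x,y Finite numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
rank_correlation <- function(x, y) {
  .check_cor_input(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Pearson correlation
#' @param x,y Finite numeric vectors of equal length >= 3.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  .check_cor_input(x, y)
  stats::cor(x, y, method = "pearson")
}

.check_cor_input <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined statistic: zero variance")
  }
  invisible(NULL)
}

#' log2 fold change with a pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; vectorized over `a`, `b`.
#'
#' @param a,b Non-negative numerators/denominators.
#' @param pseudocount Non-negative value added to both (default 0).
#' @return log2 fold change(s).
#' @export
log2_fold_change <- function(a, b, pseudocount = 0) {
  if (any(a < 0) || any(b < 0) || pseudocount < 0) {
    stop("`a`, `b` and `pseudocount` must be non-negative")
  }
  if (any(a + pseudocount <= 0) || any(b + pseudocount <= 0)) {
    stop("zero value with zero pseudocount: fold change undefined")
  }
  log2((a + pseudocount) / (b + pseudocount))
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= x)` for the number of successes in `n` draws without replacement
#' from a population of `N` with `K` successes, computed by log-space
#' summation of the point masses so that tails down to the 1e-300 range are
#' exact to machine precision.
#'
#' @param N Population size.
#' @param K Successes in the population (`K <= N`).
#' @param n Draws (`n <= N`).
#' @param x Observed successes (`x <= min(K, n)`).
#' @return An object of class `enrichment_result` with elements `N`, `K`,
#'   `n`, `x`, `p_upper_tail`.
#' @export
hypergeom_upper_tail <- function(N, K, n, x) {
  vals <- c(N = N, K = K, n = n, x = x)
  if (any(vals != round(vals)) || any(vals < 0)) {
    stop("all parameters must be non-negative integers")
  }
  if (K > N || n > N) stop("inconsistent parameters: need K <= N and n <= N")
  if (x > min(K, n)) stop("inconsistent parameters: need x <= min(K, n)")
  lo <- max(x, n - (N - K))   # support lower bound
  hi <- min(K, n)
  xs <- lo:hi
  logs <- stats::dhyper(xs, m = K, n = N - K, k = n, log = TRUE)
  m <- max(logs)
  p <- exp(m + log(sum(exp(logs - m))))
  p <- min(max(p, 0), 1)
  structure(list(N = as.integer(N), K = as.integer(K), n = as.integer(n),
                 x = as.integer(x), p_upper_tail = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: %d/%d draws in a class of %d/%d; P(X >= %d) = %.4g\n",
              x$x, x$n, x$K, x$N, x$x, x$p_upper_tail))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1), delegating to
#' `stats::p.adjust` after input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' qPCR relative quantity from delta-Ct
#'
#' `RQ = 2^dCt` where `dCt` is the target Ct normalized to a reference gene.
#'
#' @param delta_ct Finite numeric vector of delta-Ct values.
#' @return `data.frame` with columns `delta_ct` and `rq`.
#' @export
rq_from_delta_ct <- function(delta_ct) {
  if (any(!is.finite(delta_ct))) stop("delta_ct must be finite")
  data.frame(delta_ct = delta_ct, rq = 2^delta_ct)
}

#' Abundance-bias enrichment test for a picked gene set
#'
#' Dichotomizes the abundance universe at the `split` quantile (default
#' median) into high/low classes and tests, by the exact hypergeometric
#' upper tail, whether the picked genes over-represent the high class --
#' e.g. whether randomly collected single OSNs over-sample OR genes with
#' high bulk counts.
#'
#' @param abundance Named numeric vector: per-gene abundance over the
#'   universe.
#' @param picked Character vector (multiset: duplicates counted) of picked
#'   genes, all present in `abundance`.
#' @param split Quantile for the high/low cut (default 0.5).
#' @return An `enrichment_result`.
#' @export
abundance_bias_test <- function(abundance, picked, split = 0.5) {
  if (is.null(names(abundance))) stop("`abundance` must be named by gene")
  absent <- setdiff(unique(picked), names(abundance))
  if (length(absent)) {
    stop("picked gene(s) absent from abundance vector: ",
         paste(absent, collapse = ", "))
  }
  cut <- stats::quantile(abundance, probs = split, type = 7, names = FALSE)
  high <- names(abundance)[abundance > cut]
  hypergeom_upper_tail(N = length(abundance), K = length(high),
                       n = length(picked), x = sum(picked %in% high))
}
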