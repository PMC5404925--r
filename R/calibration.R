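# In-silico F1 noise calibration.  An F1 hybrid is synthesized from the
# parental samples themselves: each parent is binomially thinned to 50% of
# the median F1 depth and paired columns are summed, so the true allelic
# fold change of every gene equals the parental fold change by construction.
# Any deviation of the in-silico allelic estimates from the x = y line is
# technical noise, measured per gene and subtracted from the real F1
# estimates.

#' Build an in-silico F1 from downsampled parental samples
#'
#' Each parental sample is binomially thinned to `0.5 * median(f1_depths)`
#' (capped at the shallowest parental column total, so every column reaches
#' the same target and each allele contributes exactly half in expectation)
#' and paired B6/CAST columns are summed into total counts.  The allelic
#' counts are the known parental origins (informative fraction 1 by
#' construction), optionally thinned per gene by a supplied informative
#' fraction so that the in-silico data reproduces the real data's
#' SNP-informative coverage.
#'
#' @param b6,cast Raw `count_matrix` objects sharing the same genes.
#' @param f1_depths Numeric vector of real F1 per-sample depths (column
#'   totals).
#' @param pairing Optional two-column matrix/data.frame of
#'   `(b6_sample, cast_sample)` names; default pairs columns in index
#'   order.
#' @param informative_fraction Optional named per-gene vector in `[0, 1]`
#'   used to thin the allelic counts.
#' @param balance_or_content After depth thinning, thin the member of each
#'   pair with the larger observed OR-class total down to its partner's, so
#'   the two alleles contribute equal amounts of OSN-derived OR signal --
#'   not merely equal library depth -- and the in-silico truth sits on the
#'   x = y line even when the parental samples differ in OSN content
#'   (default `TRUE`).
#' @param seed Optional integer seed.
#' @return List with `total` (a `count_matrix`), `allelic` (an
#'   `allelic_count_table` over OR genes), `thin_fractions` (per parental
#'   sample) and `pairing`.
#' @export
build_insilico_f1 <- function(b6, cast, f1_depths, pairing = NULL,
                              informative_fraction = NULL,
                              balance_or_content = TRUE, seed = NULL) {
  stopifnot(inherits(b6, "count_matrix"), inherits(cast, "count_matrix"),
            length(f1_depths) >= 1L, all(f1_depths > 0))
  if (!identical(rownames(b6$counts), rownames(cast$counts))) {
    stop("parental matrices must share the same genes in the same order")
  }
  if (is.null(pairing)) {
    k <- min(ncol(b6$counts), ncol(cast$counts))
    pairing <- cbind(colnames(b6$counts)[seq_len(k)],
                     colnames(cast$counts)[seq_len(k)])
  } else {
    pairing <- as.matrix(pairing)
    if (ncol(pairing) != 2L || nrow(pairing) < 1L) {
      stop("`pairing` must be a non-empty two-column (b6, cast) matrix")
    }
    unknown <- c(setdiff(pairing[, 1L], colnames(b6$counts)),
                 setdiff(pairing[, 2L], colnames(cast$counts)))
    if (length(unknown)) stop("pairing references unknown sample(s): ",
                              paste(unknown, collapse = ", "))
  }
  run <- function() {
    b6_cols <- b6$counts[, pairing[, 1L], drop = FALSE]
    cast_cols <- cast$counts[, pairing[, 2L], drop = FALSE]
    tb6 <- colSums(b6_cols); tcast <- colSums(cast_cols)
    # 50% of the median F1 depth, capped at the shallowest parental sample
    # so that every column can be thinned to the same target and each
    # allele contributes exactly half in expectation.
    target <- min(0.5 * stats::median(f1_depths), tb6, tcast)
    if (target <= 0) stop("a parental sample has zero total counts")
    thin_b6 <- downsample_counts(b6_cols, target_total = target)
    thin_cast <- downsample_counts(cast_cols, target_total = target)
    if (balance_or_content) {
      or_rows <- b6$gene_class == "OR"
      for (i in seq_len(nrow(pairing))) {
        ob <- sum(thin_b6[or_rows, i])
        oc <- sum(thin_cast[or_rows, i])
        if (ob > oc && ob > 0) {
          thin_b6[, i] <- stats::rbinom(nrow(thin_b6), thin_b6[, i], oc / ob)
        } else if (oc > ob && oc > 0) {
          thin_cast[, i] <- stats::rbinom(nrow(thin_cast), thin_cast[, i], ob / oc)
        }
      }
    }
    samples <- sprintf("insilicoF1_%d", seq_len(nrow(pairing)))
    total <- thin_b6 + thin_cast
    colnames(total) <- samples
    cm <- count_matrix(total, gene_class = b6$gene_class,
                       sample_meta = data.frame(sample = samples,
                                                strain = "F1_insilico"))
    or_genes <- genes_of_class(b6, "OR")
    a1 <- thin_b6[or_genes, , drop = FALSE]
    a2 <- thin_cast[or_genes, , drop = FALSE]
    if (!is.null(informative_fraction)) {
      pi_g <- informative_fraction[or_genes]
      if (any(is.na(pi_g)) || any(pi_g < 0) || any(pi_g > 1)) {
        stop("`informative_fraction` must cover all OR genes with values in [0, 1]")
      }
      for (j in seq_len(ncol(a1))) {
        a1[, j] <- stats::rbinom(length(or_genes), a1[, j], pi_g)
        a2[, j] <- stats::rbinom(length(or_genes), a2[, j], pi_g)
      }
    }
    allelic <- allelic_count_table(data.frame(
      gene = rep(or_genes, times = length(samples)),
      sample = rep(samples, each = length(or_genes)),
      allele1_count = as.integer(a1),
      allele2_count = as.integer(a2)
    ))
    list(total = cm, allelic = allelic,
         thin_fractions = c(stats::setNames(target / tb6, pairing[, 1L]),
                            stats::setNames(target / tcast, pairing[, 2L])),
         pairing = pairing)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Per-gene technical deviation from the x = y line
#'
#' For each gene, the deviation is the mean over in-silico replicates of
#' the in-silico allelic log2 fold change minus the parental log2 fold
#' change -- the amount by which technical noise displaces an allelic
#' estimate whose truth lies exactly on the diagonal.
#'
#' @param insilico_fc Named numeric vector (one in-silico replicate) or a
#'   genes-by-replicates numeric matrix with gene row names; `NA` entries
#'   (genes unobserved in a replicate) are dropped from the mean.
#' @param parental_fc Named numeric vector of parental log2 fold changes.
#' @return `data.frame` with columns `gene`, `d` (log2 units) and
#'   `n_replicates`; attribute `omitted` lists genes absent from either
#'   side or with no finite in-silico estimate.
#' @export
compute_deviation <- function(insilico_fc, parental_fc) {
  if (is.null(names(parental_fc))) stop("`parental_fc` must be named by gene")
  if (!is.matrix(insilico_fc)) {
    if (is.null(names(insilico_fc))) stop("`insilico_fc` must be named by gene")
    insilico_fc <- matrix(insilico_fc, ncol = 1L,
                          dimnames = list(names(insilico_fc), NULL))
  }
  common <- intersect(rownames(insilico_fc), names(parental_fc))
  if (!length(common)) stop("no overlapping genes between in-silico and parental sets")
  sub <- insilico_fc[common, , drop = FALSE]
  n_rep <- rowSums(is.finite(sub))
  d <- rowMeans(sub, na.rm = TRUE) - parental_fc[common]
  ok <- n_rep > 0 & is.finite(d)
  omitted <- c(setdiff(rownames(insilico_fc), common),
               setdiff(names(parental_fc), common),
               common[!ok])
  out <- data.frame(gene = common[ok], d = as.numeric(d[ok]),
                    n_replicates = as.integer(n_rep[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, omitted = omitted)
}

#' Correct allelic fold changes for technical noise
#'
#' `corrected = raw - d` per gene.  Genes without a deviation estimate pass
#' through unchanged with `corrected = FALSE`; correction never changes
#' gene membership, only values.
#'
#' @param fc `data.frame` with columns `gene` and `allelic_log2fc_raw`
#'   (e.g. the fold-change table of a pipeline run).
#' @param deviation `data.frame` from [compute_deviation()].
#' @return `fc` with columns `allelic_log2fc_corrected` and `corrected`
#'   added or replaced.
#' @export
correct_allelic_fc <- function(fc, deviation) {
  stopifnot(all(c("gene", "allelic_log2fc_raw") %in% names(fc)),
            all(c("gene", "d") %in% names(deviation)))
  d <- stats::setNames(deviation$d, deviation$gene)
  idx <- match(fc$gene, names(d))
  has_d <- !is.na(idx)
  fc$allelic_log2fc_corrected <- fc$allelic_log2fc_raw
  fc$allelic_log2fc_corrected[has_d] <-
    fc$allelic_log2fc_raw[has_d] - as.numeric(d[idx[has_d]])
  fc$corrected <- has_d
  fc
}
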