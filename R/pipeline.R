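# End-to-end cis/trans analysis: joint depth normalization of parental and
# F1 samples, OSN-content normalization, the informative-count filter,
# allelic ratios and deconvolution, parental and allelic log2 fold changes,
# in-silico F1 calibration, corrected fold changes and concordance
# statistics.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

# Shared core: given parental matrices and an F1 (real or in-silico), run
# joint normalization and compute per-gene parental and allelic fold
# changes (allele 2 / CAST vs allele 1 / B6).
.f1_fold_changes <- function(b6, cast, f1_total, f1_allelic,
                             markers, threshold, cor_method,
                             pseudocount, osn_on_allelic) {
  combined <- combine_samples(b6, cast, f1_total)
  s <- depth_size_factors(combined)
  depth_norm <- apply_depth_normalization(combined, s)
  gate <- marker_gate(depth_norm, markers = markers, threshold = threshold,
                      method = cor_method)
  f <- osn_size_factors(depth_norm, gate$kept)
  norm <- apply_osn_normalization(depth_norm, f)
  or_genes <- genes_of_class(combined, "OR")
  b6_s <- colnames(b6$counts)
  cast_s <- colnames(cast$counts)
  f1_s <- colnames(f1_total$counts)
  m_b6 <- rowMeans(norm$counts[or_genes, b6_s, drop = FALSE])
  m_cast <- rowMeans(norm$counts[or_genes, cast_s, drop = FALSE])
  fc_parental <- stats::setNames(
    log2_fold_change(m_cast, m_b6, pseudocount), or_genes)
  ratios <- suppressMessages(allelic_ratio(
    f1_allelic, pooling = "pooled", depth_factors = s,
    osn_factors = if (osn_on_allelic) f))
  tau <- rowMeans(norm$counts[or_genes, f1_s, drop = FALSE])
  deconv <- deconvolve_alleles(tau, ratios)
  allelic_fc <- stats::setNames(
    log2_fold_change(deconv$allele2_value, deconv$allele1_value, pseudocount),
    deconv$gene)
  list(depth_factors = s, osn_factors = f, gate = gate,
       fc_parental = fc_parental, allelic_fc = allelic_fc,
       ratios = ratios, deconv = deconv,
       parental_means = list(b6 = m_b6, cast = m_cast), tau = tau)
}

.ls_slope <- function(x, y) {
  # least-squares slope of y on x
  stats::cov(x, y) / stats::var(x)
}

#' Run the full cis/trans concordance analysis
#'
#' Executes, in order: joint median-of-ratios depth normalization of
#' parental and F1 totals, OSN-content normalization of OR genes, the
#' informative-count quartile filter, pooled allelic ratios, deconvolution
#' into allele-specific expression, parental and allelic log2 fold changes
#' (CAST vs B6 orientation), in-silico F1 calibration of per-gene technical
#' deviation, corrected fold changes, and concordance statistics (Lin's ccc
#' with C_b, Pearson r, least-squares slope).
#'
#' @param b6,cast Raw parental `count_matrix` objects (same genes, OR +
#'   marker rows).
#' @param f1_total Raw F1 total `count_matrix` (same genes).
#' @param f1_allelic `allelic_count_table` of SNP-informative counts for
#'   the F1 samples (allele 1 = B6, allele 2 = CAST).
#' @param markers Marker gene ids (default: the `"marker"` rows).
#' @param marker_threshold Marker-gate correlation threshold (default 0.7).
#' @param cor_method Correlation flavor for the gate.
#' @param pseudocount Added to normalized values before log2 fold changes
#'   (default 1).
#' @param quartile Informative-filter cutoff quantile (default 0.25).
#' @param insilico_draws Number of independent in-silico F1 downsampling
#'   draws averaged into the per-gene deviation (default 50, chosen so the
#'   deviation's own sampling noise is small relative to the biases it
#'   measures).
#' @param insilico_pairing Optional `(b6_sample, cast_sample)` pairing for
#'   the in-silico F1; default index order.
#' @param osn_factors_on_allelic Apply OSN-content factors (in addition to
#'   depth factors) when normalizing SNP-informative counts (default TRUE).
#' @param seed Integer root seed for the in-silico downsampling.
#' @return An object of class `cistrans_report`.
#' @export
run_cistrans <- function(b6, cast, f1_total, f1_allelic,
                         markers = NULL, marker_threshold = 0.7,
                         cor_method = c("spearman", "pearson"),
                         pseudocount = 1, quartile = 0.25,
                         insilico_draws = 50, insilico_pairing = NULL,
                         osn_factors_on_allelic = TRUE, seed = 1) {
  cor_method <- match.arg(cor_method)
  real <- .stage("normalize+ratios", .f1_fold_changes(
    b6, cast, f1_total, f1_allelic, markers, marker_threshold, cor_method,
    pseudocount, osn_factors_on_allelic))

  kept <- .stage("informative_filter", informative_gene_filter(
    f1_allelic, depth_factors = real$depth_factors,
    osn_factors = if (osn_factors_on_allelic) real$osn_factors,
    quartile = quartile))

  # Per-gene SNP-informative fraction estimated from the real F1, used to
  # thin the in-silico allelic counts to matching coverage.
  or_genes <- genes_of_class(f1_total, "OR")
  f1_or <- f1_total$counts[or_genes, , drop = FALSE]
  inf_tot <- tapply(f1_allelic$allele1_count + f1_allelic$allele2_count,
                    f1_allelic$gene, sum)
  pi_hat <- stats::setNames(rep(0, length(or_genes)), or_genes)
  pi_hat[names(inf_tot)] <- as.numeric(inf_tot)
  tot <- rowSums(f1_or)
  pi_hat <- ifelse(tot > 0, pmin(1, pi_hat / pmax(tot, 1)), 0)

  f1_depths <- colSums(f1_total$counts)
  fc_draws <- .stage("insilico_f1", {
    draws <- matrix(NA_real_, length(or_genes), insilico_draws,
                    dimnames = list(or_genes, NULL))
    for (k in seq_len(insilico_draws)) {
      isf1 <- build_insilico_f1(b6, cast, f1_depths,
                                pairing = insilico_pairing,
                                informative_fraction = pi_hat,
                                seed = child_seed(seed, paste0("insilico_", k)))
      isr <- .f1_fold_changes(b6, cast, isf1$total, isf1$allelic,
                              markers, marker_threshold, cor_method,
                              pseudocount, osn_factors_on_allelic)
      draws[names(isr$allelic_fc), k] <- isr$allelic_fc
    }
    draws
  })
  deviation <- .stage("compute_deviation",
                      compute_deviation(fc_draws, real$fc_parental))

  fc_table <- data.frame(gene = names(real$allelic_fc),
                         parental_log2fc = real$fc_parental[names(real$allelic_fc)],
                         allelic_log2fc_raw = as.numeric(real$allelic_fc),
                         stringsAsFactors = FALSE)
  fc_table <- .stage("correct_allelic_fc",
                     correct_allelic_fc(fc_table, deviation))
  fc_table$informative <- fc_table$gene %in% kept
  fc_table <- merge(fc_table,
                    real$deconv[, c("gene", "allele1_value", "allele2_value",
                                    "total_value")],
                    by = "gene", sort = TRUE)
  rownames(fc_table) <- NULL

  use <- fc_table$informative
  if (sum(use) < 3L) stop("[stage concordance] fewer than 3 informative genes")
  x_raw <- fc_table$allelic_log2fc_raw[use]
  x_cor <- fc_table$allelic_log2fc_corrected[use]
  y <- fc_table$parental_log2fc[use]
  ccc_raw <- .stage("concordance", lin_ccc(x_raw, y, keep_pairs = FALSE))
  ccc_cor <- .stage("concordance", lin_ccc(x_cor, y, keep_pairs = FALSE))

  structure(list(
    ccc_raw = ccc_raw$ccc, ccc_corrected = ccc_cor$ccc,
    c_b_raw = ccc_raw$c_b, c_b_corrected = ccc_cor$c_b,
    pearson_raw = ccc_raw$pearson_r, pearson_corrected = ccc_cor$pearson_r,
    slope_raw = .ls_slope(y, x_raw), slope_corrected = .ls_slope(y, x_cor),
    genes_total = length(or_genes),
    genes_with_ratio = nrow(fc_table),
    genes_informative = sum(use),
    pseudocount = pseudocount, quartile = quartile,
    marker_threshold = marker_threshold, cor_method = cor_method,
    insilico_draws = insilico_draws,
    osn_factors_on_allelic = osn_factors_on_allelic,
    seed = seed,
    fc_table = fc_table, deviation = deviation, gate = real$gate,
    depth_factors = real$depth_factors, osn_factors = real$osn_factors
  ), class = "cistrans_report")
}

#' @export
print.cistrans_report <- function(x, ...) {
  cat("cis/trans concordance report\n")
  cat(sprintf("  genes: %d total OR, %d with allelic ratio, %d informative\n",
              x$genes_total, x$genes_with_ratio, x$genes_informative))
  cat(sprintf("  raw:       ccc = %.4f, C_b = %.4f, r = %.4f, slope = %.3f\n",
              x$ccc_raw, x$c_b_raw, x$pearson_raw, x$slope_raw))
  cat(sprintf("  corrected: ccc = %.4f, C_b = %.4f, r = %.4f, slope = %.3f\n",
              x$ccc_corrected, x$c_b_corrected, x$pearson_corrected,
              x$slope_corrected))
  invisible(x)
}

#' Simulate a complete cis/trans study dataset
#'
#' Generates a ground-truth repertoire model plus parental (B6, CAST) and
#' F1 count data under a given regulatory mode, mirroring the structure of
#' a two-strain + F1 hybrid design.
#'
#' @param mode `"cis"`, `"trans"` or `"mixed"` (per-gene modes from the
#'   model).
#' @param n_genes Number of OR genes.
#' @param n_parental Replicates per parental strain.
#' @param n_f1 F1 replicates.
#' @param depth Expected OR-assigned fragments per sample at full OSN
#'   content.
#' @param dispersion NB overdispersion alpha.
#' @param sigma Log-normal spread of choice probabilities.
#' @param cis_fraction Fraction of genes with a cis effect.
#' @param cis_sd SD of cis effects (log2).
#' @param trans_fraction Fraction of trans genes (used under `"mixed"`).
#' @param informative_range Range of per-gene SNP-informative fractions.
#' @param osn_fraction_range Range of per-sample OSN content.
#' @param n_background Number of non-OSN background genes.
#' @param seed Integer root seed.
#' @return List with `model`, `b6`, `cast`, `f1_total`, `f1_allelic` and
#'   `truth` (per-sample OSN fractions and F1 allele probabilities).
#' @export
simulate_cistrans_dataset <- function(mode = c("cis", "trans", "mixed"),
                                      n_genes = 1000, n_parental = 3,
                                      n_f1 = 3, depth = 2e6,
                                      dispersion = 0.05, sigma = 2,
                                      cis_fraction = 0.3, cis_sd = 1.5,
                                      trans_fraction = 0,
                                      informative_range = c(0.2, 0.8),
                                      osn_fraction_range = c(0.3, 0.9),
                                      n_background = 2000,
                                      seed = 1) {
  mode <- match.arg(mode)
  model <- repertoire_model(n_genes, sigma = sigma,
                            cis_fraction = cis_fraction, cis_sd = cis_sd,
                            trans_fraction = trans_fraction,
                            informative_range = informative_range,
                            n_background = n_background,
                            seed = child_seed(seed, "model"))
  cfg_parental <- simulation_config(n_replicates_per_group = n_parental,
                                    depth = depth, dispersion = dispersion,
                                    osn_fraction_range = osn_fraction_range,
                                    lognormal_sigma = sigma, seed = seed)
  cfg_f1 <- simulation_config(n_replicates_per_group = n_f1, depth = depth,
                              dispersion = dispersion,
                              osn_fraction_range = osn_fraction_range,
                              lognormal_sigma = sigma, seed = seed)
  b6 <- simulate_parental_counts(model, "b6", cfg_parental)
  cast <- simulate_parental_counts(model, "cast", cfg_parental)
  f1 <- simulate_f1(model, cfg_f1, mode = mode)
  list(model = model, b6 = b6$counts, cast = cast$counts,
       f1_total = f1$total, f1_allelic = f1$allelic,
       truth = list(osn_fraction = list(b6 = b6$osn_fraction,
                                        cast = cast$osn_fraction,
                                        f1 = f1$osn_fraction),
                    allele_prob = f1$allele_prob,
                    mode = mode, seed = seed))
}
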