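# Shared fixtures, all built in code.

# Tiny count matrix with explicit values for hand-checked examples.
tiny_matrix <- function(counts, classes = NULL) {
  count_matrix(counts, gene_class = classes)
}

# A small repertoire model with overridden, exactly-known probabilities.
# Used where analytic expectations matter more than realism.
exact_model <- function(p_b6, p_cast, informative = 1,
                        marker_baseline = c(Omp = 0.2, Cnga2 = 0.1),
                        n_background = 50) {
  n <- length(p_b6)
  m <- repertoire_model(n, sigma = 0, cis_fraction = 0, trans_fraction = 0,
                        informative_range = c(informative, informative),
                        marker_baseline = marker_baseline,
                        n_background = n_background, seed = 99)
  m$p_b6 <- stats::setNames(p_b6 / sum(p_b6), m$gene_ids)
  m$p_cast <- stats::setNames(p_cast / sum(p_cast), m$gene_ids)
  validate_repertoire_model(m)
  m
}

# Deterministic parental count_matrix pair with identical replicate columns
# and equal OR totals per column (no stochastic draw involved).
exact_parents <- function(b6_gene_counts, cast_gene_counts, n_rep = 3,
                          marker_count = 1000, background_count = 5000) {
  stopifnot(sum(b6_gene_counts) == sum(cast_gene_counts))
  n <- length(b6_gene_counts)
  genes <- sprintf("Olfr%04d", seq_len(n))
  build <- function(gene_counts, prefix) {
    counts <- cbind(matrix(rep(gene_counts, n_rep), ncol = n_rep),
                    deparse.level = 0)
    counts <- rbind(counts,
                    matrix(marker_count, 2L, n_rep),
                    matrix(background_count, 3L, n_rep))
    rownames(counts) <- c(genes, "Omp", "Cnga2", "Bg1", "Bg2", "Bg3")
    colnames(counts) <- sprintf("%s_%d", prefix, seq_len(n_rep))
    count_matrix(counts, gene_class = c(rep("OR", n), rep("marker", 2L),
                                        rep("other", 3L)))
  }
  list(b6 = build(b6_gene_counts, "b6"), cast = build(cast_gene_counts, "cast"))
}

# Pooled allelic log2 fold change (CAST vs B6) straight from an allelic
# table, without normalization; used as a simple oracle path in calibration
# tests.
pooled_allelic_fc <- function(allelic, pseudocount = 0) {
  s1 <- tapply(allelic$allele1_count, allelic$gene, sum)
  s2 <- tapply(allelic$allele2_count, allelic$gene, sum)
  stats::setNames(log2((as.numeric(s2) + pseudocount) /
                         (as.numeric(s1) + pseudocount)), names(s1))
}
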