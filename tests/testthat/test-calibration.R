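# In-silico F1 construction, per-gene deviation, and fold-change correction.

test_that("identical parents give allelic ratios centered on 0.5", {
  par <- exact_parents(b6_gene_counts = c(4000, 2000, 1000, 1000),
                       cast_gene_counts = c(4000, 2000, 1000, 1000))
  isf1 <- build_insilico_f1(par$b6, par$cast,
                            f1_depths = rep(sum(par$b6$counts[, 1L]), 3),
                            seed = 61)
  r <- allelic_ratio(isf1$allelic)
  for (i in seq_len(nrow(r))) {
    se <- sqrt(0.25 / r$informative_total[i])
    expect_lt(abs(r$r[i] - 0.5), 4 * se)
  }
})

test_that("a gene absent from both parents stays absent in the in-silico F1", {
  par <- exact_parents(b6_gene_counts = c(3000, 0, 1000),
                       cast_gene_counts = c(2000, 0, 2000))
  isf1 <- build_insilico_f1(par$b6, par$cast, f1_depths = rep(5000, 3),
                            seed = 63)
  g2 <- "Olfr0002"
  expect_true(all(isf1$total$counts[g2, ] == 0))
  sub <- isf1$allelic[isf1$allelic$gene == g2, ]
  expect_true(all(sub$allele1_count == 0 & sub$allele2_count == 0))
})

test_that("thinning reaches half the median F1 depth in expectation", {
  par <- exact_parents(b6_gene_counts = c(40000, 20000, 20000),
                       cast_gene_counts = c(30000, 30000, 20000),
                       n_rep = 2)
  f1_depths <- c(60000, 80000, 70000)   # median 70000, target 35000
  totals <- vapply(1:200, function(s) {
    isf1 <- build_insilico_f1(par$b6, par$cast, f1_depths,
                              balance_or_content = FALSE, seed = s)
    colSums(isf1$total$counts)[1L]
  }, numeric(1))
  target <- 2 * 35000
  expect_lt(abs(mean(totals) - target), 3 * sqrt(target) / sqrt(200))
  expect_equal(
    unname(build_insilico_f1(par$b6, par$cast, f1_depths,
                             seed = 1)$thin_fractions[1L]),
    35000 / sum(par$b6$counts[, 1L]))
})

test_that("pairing validation and reproducibility hold", {
  par <- exact_parents(b6_gene_counts = c(1000, 500),
                       cast_gene_counts = c(700, 800))
  expect_error(build_insilico_f1(par$b6, par$cast, f1_depths = 1000,
                                 pairing = cbind("nope", "cast_1")),
               "unknown sample")
  a <- build_insilico_f1(par$b6, par$cast, f1_depths = 2000, seed = 9)
  b <- build_insilico_f1(par$b6, par$cast, f1_depths = 2000, seed = 9)
  expect_identical(a$total$counts, b$total$counts)
  expect_identical(as.data.frame(a$allelic), as.data.frame(b$allelic))
})

test_that("deviation is exact arithmetic on matched gene sets", {
  d <- compute_deviation(c(g1 = 1.5, g2 = 2), c(g1 = 1.0, g2 = 2))
  expect_equal(d$d[d$gene == "g1"], 0.5)
  expect_equal(d$d[d$gene == "g2"], 0)
  m <- matrix(c(1, 2, 3, 5), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  d2 <- compute_deviation(m, c(g1 = 2, g2 = 3, g3 = 1))
  expect_equal(d2$d[d2$gene == "g1"], 0)
  expect_equal(d2$d[d2$gene == "g2"], 0.5)
  expect_true("g3" %in% attr(d2, "omitted"))
  expect_error(compute_deviation(c(gA = 1), c(gB = 1)), "overlap")
})

test_that("deviation vanishes exactly when thinning is a pass-through", {
  # f1 depth twice the parental totals => thinning fraction 1, no noise
  par <- exact_parents(b6_gene_counts = c(400, 200, 200, 200),
                       cast_gene_counts = c(200, 400, 200, 200))
  tot <- sum(par$b6$counts[, 1L])
  isf1 <- build_insilico_f1(par$b6, par$cast, f1_depths = rep(2 * tot, 3),
                            seed = 67)
  insilico_fc <- pooled_allelic_fc(isf1$allelic)
  genes <- sprintf("Olfr%04d", 1:4)
  parental_fc <- log2(par$cast$counts[genes, 1L] / par$b6$counts[genes, 1L])
  d <- compute_deviation(insilico_fc, parental_fc)
  expect_true(all(abs(d$d) < 1e-12))
})

test_that("finite-depth deviations are unbiased over repeated draws", {
  par <- exact_parents(b6_gene_counts = c(40000, 20000, 10000, 8000, 6000),
                       cast_gene_counts = c(20000, 30000, 15000, 8000, 11000))
  tot <- sum(par$b6$counts[, 1L])
  genes <- sprintf("Olfr%04d", 1:5)
  parental_fc <- log2(par$cast$counts[genes, 1L] / par$b6$counts[genes, 1L])
  per_seed <- vapply(1:100, function(s) {
    isf1 <- build_insilico_f1(par$b6, par$cast, f1_depths = rep(tot, 3),
                              seed = s)
    fc <- pooled_allelic_fc(isf1$allelic)
    mean(fc[genes] - parental_fc)
  }, numeric(1))
  expect_lt(abs(mean(per_seed)), 3 * sd(per_seed) / sqrt(100))
})

test_that("correction subtracts deviations without changing membership", {
  fc <- data.frame(gene = c("g1", "g2", "g3"),
                   allelic_log2fc_raw = c(2, -1, 0.5))
  dev <- data.frame(gene = c("g1", "g2"), d = c(0.5, 0))
  out <- correct_allelic_fc(fc, dev)
  expect_equal(out$allelic_log2fc_corrected, c(1.5, -1, 0.5))
  expect_equal(out$corrected, c(TRUE, TRUE, FALSE))
  expect_identical(out$gene, fc$gene)
  ident <- correct_allelic_fc(fc, data.frame(gene = fc$gene, d = c(0, 0, 0)))
  expect_equal(ident$allelic_log2fc_corrected, fc$allelic_log2fc_raw)
})

test_that("correction is exact on the in-silico data itself", {
  par <- exact_parents(b6_gene_counts = c(3000, 1500, 900, 600),
                       cast_gene_counts = c(1500, 2400, 1200, 900))
  tot <- sum(par$b6$counts[, 1L])
  genes <- sprintf("Olfr%04d", 1:4)
  parental_fc <- log2(par$cast$counts[genes, 1L] / par$b6$counts[genes, 1L])
  fcs <- vapply(1:20, function(s) {
    isf1 <- build_insilico_f1(par$b6, par$cast, f1_depths = rep(tot, 3),
                              seed = s)
    pooled_allelic_fc(isf1$allelic)[genes]
  }, numeric(4))
  d <- compute_deviation(fcs, parental_fc)
  raw <- data.frame(gene = genes, allelic_log2fc_raw = rowMeans(fcs))
  corrected <- correct_allelic_fc(raw, d)
  # mean corrected in-silico fold change returns exactly to the parental one
  expect_equal(corrected$allelic_log2fc_corrected,
               unname(parental_fc[corrected$gene]), tolerance = 1e-12)
})
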