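# Synthetic-data generator: choice probabilities, parental and F1 counts,
# binomial downsampling.

test_that("choice probabilities are a valid, reproducible distribution", {
  p <- draw_choice_probabilities(4, sigma = 0, seed = 1)
  expect_equal(p, rep(0.25, 4))
  for (s in 1:5) {
    p <- draw_choice_probabilities(1000, sigma = 2, seed = s)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_identical(draw_choice_probabilities(100, 2, seed = 7),
                   draw_choice_probabilities(100, 2, seed = 7))
  expect_error(draw_choice_probabilities(1, 1), "n_genes")
  expect_error(draw_choice_probabilities(10, -0.1), "sigma")
})

test_that("sigma = 2 reproduces the dominant-subtype skew", {
  # a quarter of the repertoire should be carried by at most 5% of genes
  hits <- 0L
  for (s in 1:100) {
    p <- sort(draw_choice_probabilities(1000, sigma = 2, seed = s),
              decreasing = TRUE)
    n_top <- which(cumsum(p) >= 0.25)[1L]
    if (n_top <= 50L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("parental counts match the Poisson limit at zero dispersion", {
  model <- repertoire_model(100, sigma = 0, cis_fraction = 0, seed = 3)
  cfg <- simulation_config(n_replicates_per_group = 2, depth = 1e7,
                           dispersion = 0, osn_fraction_range = c(1, 1),
                           seed = 3)
  sim <- simulate_parental_counts(model, "b6", cfg)
  or <- sim$counts$counts[model$gene_ids, ]
  p_hat <- or / 1e7
  se <- sqrt(0.01 / 1e7)
  within3 <- abs(p_hat - 0.01) <= 3 * se
  expect_gte(mean(within3), 0.95)
  expect_lt(abs(mean(p_hat) - 0.01), 3 * se / sqrt(length(p_hat)))
})

test_that("a cis factor of 2 doubles the strain mean before renormalization", {
  model <- exact_model(p_b6 = c(1, 1, 1, 1), p_cast = c(2, 1, 1, 1))
  cfg <- simulation_config(n_replicates_per_group = 4, depth = 1e7,
                           dispersion = 0, osn_fraction_range = c(1, 1),
                           seed = 5)
  b6 <- simulate_parental_counts(model, "b6", cfg)
  cast <- simulate_parental_counts(model, "cast", cfg)
  g1 <- model$gene_ids[1L]
  ratio <- mean(cast$counts$counts[g1, ]) / mean(b6$counts$counts[g1, ])
  # 2 times the cis factor, divided by the renormalization constant 5/4
  expect_equal(ratio, 2 / (5 / 4), tolerance = 0.02)
})

test_that("OR column sums concentrate around the configured depth", {
  model <- repertoire_model(300, sigma = 2, cis_fraction = 0, seed = 11)
  cfg <- simulation_config(n_replicates_per_group = 50, depth = 1e6,
                           dispersion = 0.05, osn_fraction_range = c(1, 1),
                           seed = 11)
  sim <- simulate_parental_counts(model, "b6", cfg)
  or_totals <- colSums(sim$counts$counts[model$gene_ids, ])
  mu <- 1e6 * model$p_b6
  sd_total <- sqrt(sum(mu + 0.05 * mu^2))
  expect_lt(abs(mean(or_totals) - 1e6), 3 * sd_total / sqrt(50))
})

test_that("F1 allelic ratios follow the cis and trans analytic expectations", {
  model <- exact_model(p_b6 = c(2, 1, 1, 1), p_cast = c(1, 1, 1, 2))
  cfg <- simulation_config(n_replicates_per_group = 3, depth = 1e7,
                           dispersion = 0, osn_fraction_range = c(1, 1),
                           seed = 7)
  cis <- simulate_f1(model, cfg, mode = "cis")
  r <- allelic_ratio(cis$allelic)
  g1 <- model$gene_ids[1L]
  # p_b6 = 2 p_cast for gene 1: expected allele-1 share 2/3
  tol <- 3 / sqrt(r$informative_total[r$gene == g1])
  expect_equal(r$r[r$gene == g1], 2 / 3, tolerance = tol)
  trans <- simulate_f1(model, cfg, mode = "trans")
  rt <- allelic_ratio(trans$allelic)
  for (g in model$gene_ids) {
    tol <- 3 / sqrt(rt$informative_total[rt$gene == g])
    expect_equal(rt$r[rt$gene == g], 0.5, tolerance = tol)
  }
})

test_that("informative counts equal totals when pi = 1 and never exceed them", {
  model <- repertoire_model(50, sigma = 1, informative_range = c(1, 1),
                            n_background = 20, seed = 13)
  cfg <- simulation_config(n_replicates_per_group = 3, depth = 1e5, seed = 13)
  f1 <- simulate_f1(model, cfg, mode = "cis")
  inf <- tapply(f1$allelic$allele1_count + f1$allelic$allele2_count,
                f1$allelic$sample, sum)
  tot <- colSums(f1$total$counts[model$gene_ids, ])
  expect_equal(as.numeric(inf[names(tot)]), as.numeric(tot))
  model2 <- repertoire_model(50, sigma = 1, informative_range = c(0.2, 0.6),
                             n_background = 20, seed = 13)
  f2 <- simulate_f1(model2, cfg, mode = "cis")
  a <- f2$allele_counts
  expect_true(all(f2$allelic$allele1_count <= as.integer(a$allele1)))
  expect_true(all(f2$allelic$allele2_count <= as.integer(a$allele2)))
})

test_that("simulated counts match negative-binomial moments", {
  model <- exact_model(p_b6 = rep(1, 5), p_cast = rep(1, 5))
  cfg <- simulation_config(n_replicates_per_group = 200, depth = 1e5,
                           dispersion = 0.1, osn_fraction_range = c(1, 1),
                           seed = 17)
  sim <- simulate_parental_counts(model, "b6", cfg)
  x <- sim$counts$counts[model$gene_ids[1L], ]
  mu <- 1e5 * 0.2
  v <- mu + 0.1 * mu^2
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / 200))
  expect_gt(var(x) / v, 0.6)
  expect_lt(var(x) / v, 1.6)
})

test_that("downsampling has exact identity, zero and moment behavior", {
  model <- repertoire_model(30, sigma = 1, n_background = 10, seed = 19)
  cfg <- simulation_config(n_replicates_per_group = 2, depth = 1e4, seed = 19)
  x <- simulate_parental_counts(model, "b6", cfg)$counts
  expect_identical(downsample_counts(x, fraction = 1, seed = 1)$counts,
                   x$counts)
  expect_true(all(downsample_counts(x, fraction = 0, seed = 1)$counts == 0))
  T0 <- colSums(x$counts)[1L]
  totals <- vapply(1:200, function(s) {
    colSums(downsample_counts(x, fraction = 0.5, seed = s)$counts)[1L]
  }, numeric(1))
  expect_lt(abs(mean(totals) - T0 / 2), 3 * sqrt(0.25 * T0) / sqrt(200))
  expect_error(downsample_counts(x, target_total = max(colSums(x$counts)) + 1),
               "exceeds")
  expect_identical(downsample_counts(x, fraction = 0.3, seed = 42)$counts,
                   downsample_counts(x, fraction = 0.3, seed = 42)$counts)
})

test_that("identical seed and config give bit-identical datasets", {
  d1 <- simulate_cistrans_dataset("cis", n_genes = 60, depth = 1e5, seed = 21)
  d2 <- simulate_cistrans_dataset("cis", n_genes = 60, depth = 1e5, seed = 21)
  expect_identical(d1$b6$counts, d2$b6$counts)
  expect_identical(d1$cast$counts, d2$cast$counts)
  expect_identical(d1$f1_total$counts, d2$f1_total$counts)
  expect_identical(as.data.frame(d1$f1_allelic), as.data.frame(d2$f1_allelic))
})

test_that("model invariants hold and bad arguments are rejected", {
  m <- repertoire_model(200, sigma = 1.5, cis_fraction = 0.2,
                        trans_fraction = 0.2, seed = 23)
  expect_lt(abs(sum(m$p_b6) - 1), 1e-12)
  expect_lt(abs(sum(m$p_cast) - 1), 1e-12)
  expect_length(intersect(names(m$cis_effects), m$trans_genes), 0)
  expect_true(all(m$informative_fraction >= 0 & m$informative_fraction <= 1))
  cfg <- simulation_config(seed = 1)
  expect_error(simulate_parental_counts(m, "129", cfg), "unknown strain")
})
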