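# Depth (median-of-ratios) and OSN-content (marker-gene) normalization.

test_that("depth size factors reproduce hand-computed median-of-ratios", {
  # identical columns: all factors exactly 1
  m <- tiny_matrix(matrix(c(5, 10, 20, 5, 10, 20), ncol = 2,
                          dimnames = list(paste0("g", 1:3), c("a", "b"))))
  expect_equal(as.numeric(depth_size_factors(m)), c(1, 1))

  # column 2 = 3 x column 1: s = (1/sqrt(3), sqrt(3))
  set.seed(1)
  base <- rpois(50, 100) + 1
  two <- cbind(a = base, b = 3 * base)
  rownames(two) <- paste0("g", 1:50)
  s2 <- depth_size_factors(tiny_matrix(two))
  expect_equal(as.numeric(s2), c(1 / sqrt(3), sqrt(3)), tolerance = 1e-12)

  # single usable gene (4, 9): reference 6, s = (2/3, 3/2)
  m3 <- tiny_matrix(matrix(c(4, 0, 9, 7), ncol = 2,
                           dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_equal(as.numeric(depth_size_factors(m3)), c(2 / 3, 3 / 2),
               tolerance = 1e-12)

  # no gene nonzero everywhere: degenerate
  m4 <- tiny_matrix(matrix(c(1, 0, 0, 2), ncol = 2,
                           dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_error(depth_size_factors(m4), "degenerate")
})

test_that("depth size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  ds <- simulate_cistrans_dataset("cis", n_genes = 200, depth = 1e5, seed = 31)
  combined <- combine_samples(ds$b6, ds$cast, ds$f1_total)
  ours <- as.numeric(depth_size_factors(combined))
  theirs <- DESeq2::estimateSizeFactorsForMatrix(combined$counts)
  # identical up to the geometric-mean-one rescaling convention
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-10)
})

test_that("depth factors are scale-equivariant and idempotent", {
  ds <- simulate_cistrans_dataset("cis", n_genes = 300, depth = 1e5, seed = 33)
  x <- ds$b6
  s0 <- depth_size_factors(x)
  scaled <- x
  scaled$counts[, 2L] <- round(scaled$counts[, 2L] * 5)
  s1 <- depth_size_factors(scaled)
  expect_equal((s1[[2L]] / s1[[1L]]) / (s0[[2L]] / s0[[1L]]), 5,
               tolerance = 0.02)
  norm <- apply_depth_normalization(x, s0)
  s_again <- depth_size_factors(norm)
  expect_true(all(abs(as.numeric(s_again) - 1) < 1e-9))
})

test_that("marker gate keeps tracking markers and drops flat or inverted ones", {
  or_vals <- matrix(c(10, 20, 30, 40), nrow = 1)
  counts <- rbind(or_vals,                      # OR gene
                  2 * or_vals,                  # proportional marker
                  matrix(5, 1, 4),              # constant marker
                  or_vals[, 4:1])               # anti-correlated marker
  dimnames(counts) <- list(c("g1", "Omp", "Adcy3", "Gnal"),
                           paste0("s", 1:4))
  m <- count_matrix(counts, gene_class = c("OR", "marker", "marker", "marker"),
                    normalized = TRUE)
  expect_warning(gate <- marker_gate(m, threshold = 0.7), "Adcy3")
  expect_identical(gate$kept, "Omp")
  expect_equal(unname(gate$correlations["Omp"]), 1)
  expect_equal(unname(gate$correlations["Gnal"]), -1)
  # all markers failing is a hard gate error
  m2 <- m
  m2$counts <- m2$counts[c("g1", "Gnal"), ]
  m2$gene_class <- m2$gene_class[c("g1", "Gnal")]
  expect_error(marker_gate(m2, threshold = 0), "gate failure")
})

test_that("OSN size factors follow the geometric-mean formula", {
  mk <- function(g) {
    counts <- rbind(g, g, matrix(1, 1, length(g)))
    dimnames(counts) <- list(c("Omp", "Cnga2", "g1"),
                             paste0("s", seq_along(g)))
    count_matrix(counts, gene_class = c("marker", "marker", "OR"),
                 normalized = TRUE)
  }
  f <- osn_size_factors(mk(c(10, 20)), c("Omp", "Cnga2"))
  expect_equal(as.numeric(f), c(1.5, 0.75), tolerance = 1e-12)
  f2 <- osn_size_factors(mk(c(8, 27, 64)), c("Omp", "Cnga2"))
  expect_equal(as.numeric(f2), c(33 / 8, 33 / 27, 33 / 64), tolerance = 1e-12)
  f3 <- osn_size_factors(mk(c(7, 7, 7)), c("Omp", "Cnga2"))
  expect_equal(as.numeric(f3), c(1, 1, 1))
  bad <- mk(c(5, 0))
  expect_error(osn_size_factors(bad, c("Omp", "Cnga2")), "s2")
})

test_that("OSN normalization rescales OR rows only", {
  counts <- matrix(c(100, 50, 200, 60), ncol = 2,
                   dimnames = list(c("g1", "Omp"), c("a", "b")))
  m <- count_matrix(counts, gene_class = c("OR", "marker"), normalized = TRUE)
  f <- size_factors(c(a = 1.5, b = 0.5), kind = "osn_content")
  out <- apply_osn_normalization(m, f)
  expect_equal(out$counts["g1", ], c(a = 150, b = 100))
  expect_equal(out$counts["Omp", ], counts["Omp", ])
  ident <- apply_osn_normalization(m, size_factors(c(a = 1, b = 1),
                                                   kind = "osn_content"))
  expect_equal(ident$counts, counts)
  expect_error(apply_osn_normalization(m, size_factors(c(a = 1),
                                                       kind = "osn_content")),
               "missing")
})

test_that("two-stage normalization strongly reduces OSN-content variation", {
  model <- repertoire_model(200, sigma = 0, cis_fraction = 0, seed = 35)
  cfg <- simulation_config(n_replicates_per_group = 12, depth = 1e6,
                           dispersion = 0.01, osn_fraction_range = c(0.3, 0.9),
                           seed = 35)
  sim <- simulate_parental_counts(model, "b6", cfg)
  res <- normalize_two_stage(sim$counts)
  depth_only <- apply_depth_normalization(sim$counts, res$depth_factors)
  cv <- function(v) sd(v) / mean(v)
  cv_before <- median(apply(depth_only$counts[model$gene_ids, ], 1L, cv))
  cv_after <- median(apply(res$normalized$counts[model$gene_ids, ], 1L, cv))
  expect_gt(cv_before, 0.2)
  expect_lt(cv_after, cv_before / 2)
})
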