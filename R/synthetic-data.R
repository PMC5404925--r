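# Synthetic OSN repertoire data with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a heavy-tailed distribution of OR-choice probabilities (a few OSN
# subtypes dominate the repertoire), per-strain cis effects acting
# multiplicatively on choice probabilities, F1 hybrids whose allele-choice
# probabilities follow the cis or trans model, SNP-informative fractions
# per gene, marker genes tracking per-sample OSN content, and
# negative-binomial sequencing noise.

#' Draw OR-choice probabilities from a log-normal competition model
#'
#' OR gene choice is modeled as a competition over a fixed OSN pool: each
#' gene receives weight `exp(Normal(0, sigma^2))` and probabilities are the
#' normalized weights.  One parameter (`sigma`) reproduces the observed skew
#' in which a few percent of OSN subtypes carry a quarter of all neurons.
#'
#' @param n_genes Number of OR genes (>= 2).
#' @param sigma Log-normal spread (>= 0); `sigma = 0` gives the uniform
#'   repertoire.
#' @param seed Optional integer seed.
#' @return Numeric probability vector of length `n_genes` summing to 1.
#' @export
draw_choice_probabilities <- function(n_genes, sigma, seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 2) {
    stop("`n_genes` must be a single count >= 2")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single value >= 0")
  }
  draw <- function() {
    w <- exp(stats::rnorm(n_genes, mean = 0, sd = sigma))
    w / sum(w)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Ground-truth repertoire model for the simulator
#'
#' Holds per-strain OR-choice probabilities, the cis-effect and trans-gene
#' assignments (disjoint), per-gene SNP-informative fractions and marker-gene
#' baselines.
#'
#' @param n_genes Number of OR genes.
#' @param sigma Log-normal spread of choice probabilities (default 2, which
#'   places a quarter of the repertoire in a few percent of genes).
#' @param cis_fraction Fraction of genes given a cis effect.
#' @param cis_sd Standard deviation of cis effects on the log2 scale.
#' @param trans_fraction Fraction of genes (disjoint from the cis set) whose
#'   F1 alleles are equalized under `mode = "mixed"`.
#' @param informative_range Range of the per-gene SNP-informative fraction
#'   `pi_g` (uniform draw).
#' @param marker_baseline Named vector of expected marker-gene expression per
#'   unit OSN content, as a fraction of sequencing depth.
#' @param n_background Number of non-OSN background genes.  Whole-mucosa
#'   libraries are dominated by transcripts from cells other than mature
#'   OSNs; these genes do not scale with OSN content and are what anchors
#'   the depth normalization, keeping it separable from the OSN-content
#'   normalization.
#' @param background_sigma Log-normal spread of background baselines.
#' @param background_scale Total background expression relative to the
#'   OR-assigned depth (default 3: non-OSN RNA outweighs OR reads).
#' @param seed Integer seed.
#' @return An object of class `repertoire_model`.
#' @export
repertoire_model <- function(n_genes,
                             sigma = 2,
                             cis_fraction = 0.3,
                             cis_sd = 1.5,
                             trans_fraction = 0,
                             informative_range = c(0.2, 0.8),
                             marker_baseline = c(Omp = 0.15, Adcy3 = 0.08,
                                                 Ano2 = 0.06, Cnga2 = 0.05,
                                                 Gnal = 0.05),
                             n_background = 2000,
                             background_sigma = 1,
                             background_scale = 3,
                             seed = 1) {
  stopifnot(cis_fraction >= 0, trans_fraction >= 0,
            cis_fraction + trans_fraction <= 1,
            length(informative_range) == 2L,
            all(informative_range >= 0), all(informative_range <= 1),
            !is.null(names(marker_baseline)), all(marker_baseline > 0))
  gene_ids <- sprintf("Olfr%04d", seq_len(n_genes))
  p_b6 <- stats::setNames(
    draw_choice_probabilities(n_genes, sigma, seed = child_seed(seed, "p_b6")),
    gene_ids
  )
  model <- with_seed(child_seed(seed, "effects"), {
    n_cis <- round(cis_fraction * n_genes)
    n_trans <- round(trans_fraction * n_genes)
    cis_genes <- sort(sample(gene_ids, n_cis))
    trans_genes <- sort(sample(setdiff(gene_ids, cis_genes), n_trans))
    cis_effects <- stats::setNames(stats::rnorm(n_cis, 0, cis_sd), cis_genes)
    informative_fraction <- stats::setNames(
      stats::runif(n_genes, informative_range[1L], informative_range[2L]),
      gene_ids
    )
    list(cis_effects = cis_effects, trans_genes = trans_genes,
         informative_fraction = informative_fraction)
  })
  effect_vec <- stats::setNames(rep(0, n_genes), gene_ids)
  effect_vec[names(model$cis_effects)] <- model$cis_effects
  p_cast <- p_b6 * 2^effect_vec
  p_cast <- p_cast / sum(p_cast)
  background_baseline <- if (n_background > 0) {
    w <- with_seed(child_seed(seed, "background"),
                   exp(stats::rnorm(n_background, 0, background_sigma)))
    stats::setNames(background_scale * w / sum(w),
                    sprintf("Bg%04d", seq_len(n_background)))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  out <- structure(
    list(n_genes = as.integer(n_genes), gene_ids = gene_ids,
         p_b6 = p_b6, p_cast = p_cast,
         cis_effects = model$cis_effects, trans_genes = model$trans_genes,
         informative_fraction = model$informative_fraction,
         marker_baseline = marker_baseline,
         background_baseline = background_baseline,
         sigma = sigma, seed = seed),
    class = "repertoire_model"
  )
  validate_repertoire_model(out)
  out
}

#' Validate repertoire-model invariants
#'
#' Checks that each strain's choice probabilities sum to one, informative
#' fractions lie in `[0, 1]`, and the cis and trans gene sets are disjoint.
#'
#' @param model A `repertoire_model`.
#' @return The model, invisibly; errors if an invariant is violated.
#' @export
validate_repertoire_model <- function(model) {
  stopifnot(inherits(model, "repertoire_model"))
  for (p in list(model$p_b6, model$p_cast)) {
    if (abs(sum(p) - 1) > 1e-12 || any(p < 0)) {
      stop("choice probabilities must be non-negative and sum to 1")
    }
  }
  pi_g <- model$informative_fraction
  if (any(pi_g < 0) || any(pi_g > 1)) stop("informative fractions must lie in [0, 1]")
  if (length(intersect(names(model$cis_effects), model$trans_genes))) {
    stop("cis-effect and trans gene sets must be disjoint")
  }
  invisible(model)
}

#' Simulation configuration
#'
#' @param n_replicates_per_group Replicates per strain/condition.
#' @param depth Expected OR-assigned fragments per sample at full OSN content.
#' @param dispersion Negative-binomial overdispersion `alpha >= 0`
#'   (`var = mu + alpha * mu^2`); 0 is Poisson.
#' @param marker_dispersion Overdispersion of the marker genes (default
#'   0.005).  Markers are by definition stably expressed in mature OSNs --
#'   that is what qualifies them for content normalization -- so their
#'   biological variability is far below that of individual OR genes.
#' @param osn_fraction_range Per-sample OSN content drawn uniformly from this
#'   interval in `(0, 1]`; both OR and marker reads scale with it.
#' @param lognormal_sigma Spread of choice probabilities (kept with the
#'   config for provenance).
#' @param seed Integer root seed; identical seed + config gives bit-identical
#'   output.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_replicates_per_group = 3,
                              depth = 2e6,
                              dispersion = 0.05,
                              marker_dispersion = 0.005,
                              osn_fraction_range = c(0.3, 0.9),
                              lognormal_sigma = 2,
                              seed = 1) {
  stopifnot(n_replicates_per_group >= 1, depth > 0, dispersion >= 0,
            marker_dispersion >= 0,
            length(osn_fraction_range) == 2L,
            osn_fraction_range[1L] > 0, osn_fraction_range[2L] <= 1,
            osn_fraction_range[1L] <= osn_fraction_range[2L])
  structure(
    list(n_replicates_per_group = as.integer(n_replicates_per_group),
         depth = depth, dispersion = dispersion,
         marker_dispersion = marker_dispersion,
         osn_fraction_range = osn_fraction_range,
         lognormal_sigma = lognormal_sigma, seed = seed),
    class = "simulation_config"
  )
}

# Marker rows for one set of samples: mean = baseline * osn_fraction * depth.
.marker_counts <- function(model, osn_fraction, depth, alpha) {
  nb <- length(model$marker_baseline)
  vapply(seq_along(osn_fraction), function(j) {
    mu <- model$marker_baseline * osn_fraction[j] * depth
    rnb(nb, mu, alpha)
  }, numeric(nb))
}

# Background (non-OSN) rows: mean = baseline * depth, independent of OSN
# content.
.background_counts <- function(model, n_samples, depth, alpha) {
  nb <- length(model$background_baseline)
  if (nb == 0L) return(matrix(numeric(0), 0L, n_samples))
  vapply(seq_len(n_samples), function(j) {
    rnb(nb, model$background_baseline * depth, alpha)
  }, numeric(nb))
}

.append_classes <- function(model) {
  c(rep("OR", model$n_genes),
    rep("marker", length(model$marker_baseline)),
    rep("other", length(model$background_baseline)))
}

#' Simulate parental (F0) OR count data
#'
#' Per gene and replicate, counts are negative-binomial with mean
#' `depth * osn_fraction_j * p_g` for the requested strain; marker-gene rows
#' are appended with mean `baseline * osn_fraction_j * depth` so that both
#' OR and marker reads scale with the sample's OSN content (the premise of
#' the marker-based normalization).
#'
#' @param model A `repertoire_model`.
#' @param strain `"b6"` or `"cast"`.
#' @param config A `simulation_config`.
#' @return List with `counts` (a `count_matrix` of OR + marker rows),
#'   `osn_fraction` (per-sample ground truth) and `means` (expected counts).
#' @export
simulate_parental_counts <- function(model, strain, config) {
  stopifnot(inherits(model, "repertoire_model"),
            inherits(config, "simulation_config"))
  if (!strain %in% c("b6", "cast")) {
    stop("unknown strain label: ", strain, " (expected 'b6' or 'cast')")
  }
  p <- if (strain == "b6") model$p_b6 else model$p_cast
  nrep <- config$n_replicates_per_group
  with_seed(child_seed(config$seed, paste0("parental_", strain)), {
    osn_fraction <- stats::runif(nrep, config$osn_fraction_range[1L],
                                 config$osn_fraction_range[2L])
    means <- outer(p, osn_fraction * config$depth)
    or_counts <- matrix(rnb(length(means), as.vector(means), config$dispersion),
                        nrow = nrow(means))
    marker <- .marker_counts(model, osn_fraction, config$depth, config$marker_dispersion)
    background <- .background_counts(model, nrep, config$depth, config$dispersion)
    counts <- rbind(or_counts, marker, background)
    rownames(counts) <- c(model$gene_ids, names(model$marker_baseline),
                          names(model$background_baseline))
    colnames(counts) <- sprintf("%s_%d", strain, seq_len(nrep))
    cm <- count_matrix(
      counts,
      gene_class = .append_classes(model),
      sample_meta = data.frame(sample = colnames(counts), strain = strain)
    )
    list(counts = cm,
         osn_fraction = stats::setNames(osn_fraction, colnames(counts)),
         means = means)
  })
}

#' Simulate F1 hybrid total and allelic OR counts
#'
#' Allele-choice probabilities follow the cis or trans model: a cis gene's
#' alleles keep the parental choice probabilities halved,
#' `(p_b6/2, p_cast/2)`; a trans gene's alleles are equalized at
#' `(p_b6 + p_cast)/4` each.  The vector over all alleles is renormalized,
#' allele counts are negative-binomial, total counts are the exact sum of
#' the two allele counts, and SNP-informative counts are binomial thinnings
#' of the allele counts with the per-gene informative fraction `pi_g`.
#'
#' @param model A `repertoire_model`.
#' @param config A `simulation_config`.
#' @param mode `"cis"` (all genes cis), `"trans"` (all genes trans) or
#'   `"mixed"` (each gene's mode taken from the model's `trans_genes`).
#' @return List with `total` (a `count_matrix` of OR + marker rows),
#'   `allelic` (an `allelic_count_table` of informative counts),
#'   `allele_counts` (true per-allele counts), `allele_prob` (ground-truth
#'   allele-choice probabilities) and `osn_fraction`.
#' @export
simulate_f1 <- function(model, config, mode = c("mixed", "cis", "trans")) {
  stopifnot(inherits(model, "repertoire_model"),
            inherits(config, "simulation_config"))
  mode <- match.arg(mode)
  is_trans <- switch(mode,
    cis = rep(FALSE, model$n_genes),
    trans = rep(TRUE, model$n_genes),
    mixed = model$gene_ids %in% model$trans_genes
  )
  q1 <- ifelse(is_trans, (model$p_b6 + model$p_cast) / 4, model$p_b6 / 2)
  q2 <- ifelse(is_trans, (model$p_b6 + model$p_cast) / 4, model$p_cast / 2)
  z <- sum(q1) + sum(q2)
  q1 <- q1 / z
  q2 <- q2 / z
  nrep <- config$n_replicates_per_group
  pi_g <- model$informative_fraction
  with_seed(child_seed(config$seed, paste0("f1_", mode)), {
    osn_fraction <- stats::runif(nrep, config$osn_fraction_range[1L],
                                 config$osn_fraction_range[2L])
    samples <- sprintf("f1_%d", seq_len(nrep))
    a1 <- a2 <- i1 <- i2 <- matrix(0L, model$n_genes, nrep,
                                   dimnames = list(model$gene_ids, samples))
    for (j in seq_len(nrep)) {
      scale_j <- config$depth * osn_fraction[j]
      a1[, j] <- rnb(model$n_genes, scale_j * q1, config$dispersion)
      a2[, j] <- rnb(model$n_genes, scale_j * q2, config$dispersion)
      i1[, j] <- stats::rbinom(model$n_genes, a1[, j], pi_g)
      i2[, j] <- stats::rbinom(model$n_genes, a2[, j], pi_g)
    }
    marker <- .marker_counts(model, osn_fraction, config$depth, config$marker_dispersion)
    background <- .background_counts(model, nrep, config$depth, config$dispersion)
    total <- rbind(a1 + a2, marker, background)
    rownames(total) <- c(model$gene_ids, names(model$marker_baseline),
                         names(model$background_baseline))
    colnames(total) <- samples
    cm <- count_matrix(
      total,
      gene_class = .append_classes(model),
      sample_meta = data.frame(sample = samples, strain = "F1")
    )
    allelic <- allelic_count_table(data.frame(
      gene = rep(model$gene_ids, times = nrep),
      sample = rep(samples, each = model$n_genes),
      allele1_count = as.integer(i1),
      allele2_count = as.integer(i2)
    ))
    list(total = cm, allelic = allelic,
         allele_counts = list(allele1 = a1, allele2 = a2),
         allele_prob = list(allele1 = stats::setNames(q1, model$gene_ids),
                            allele2 = stats::setNames(q2, model$gene_ids)),
         osn_fraction = stats::setNames(osn_fraction, samples))
  })
}

#' Binomially downsample a count matrix
#'
#' The count-level equivalent of read subsampling: each count `c` becomes
#' `Binomial(c, q)` with `q` either a global `fraction` or
#' `target_total / column_total` per sample.
#'
#' @param x A `count_matrix` (raw counts) or integer matrix.
#' @param fraction Thinning probability in `[0, 1]`, applied to every cell.
#' @param target_total Target column total; must not exceed any current
#'   column total.  Exactly one of `fraction`/`target_total` must be given.
#' @param seed Optional integer seed.
#' @return Same type as `x`, thinned.
#' @export
downsample_counts <- function(x, fraction = NULL, target_total = NULL,
                              seed = NULL) {
  is_cm <- inherits(x, "count_matrix")
  counts <- if (is_cm) x$counts else x
  stopifnot(is.matrix(counts))
  if (is.null(fraction) == is.null(target_total)) {
    stop("give exactly one of `fraction` or `target_total`")
  }
  if (!is.null(fraction)) {
    if (fraction < 0 || fraction > 1) stop("`fraction` must lie in [0, 1]")
    q <- rep(fraction, ncol(counts))
  } else {
    totals <- colSums(counts)
    if (any(target_total > totals)) {
      stop("`target_total` exceeds the column total of sample(s): ",
           paste(colnames(counts)[target_total > totals], collapse = ", "))
    }
    q <- target_total / totals
  }
  thin <- function() {
    out <- counts
    for (j in seq_len(ncol(counts))) {
      out[, j] <- stats::rbinom(nrow(counts), counts[, j], q[j])
    }
    out
  }
  thinned <- if (is.null(seed)) thin() else with_seed(seed, thin())
  if (is_cm) {
    count_matrix(thinned, gene_class = x$gene_class,
                 sample_meta = x$sample_meta, normalized = FALSE)
  } else {
    thinned
  }
}
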