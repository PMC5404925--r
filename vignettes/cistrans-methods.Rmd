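---
title: "Measuring OSN repertoires and dissecting cis from trans regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring OSN repertoires and dissecting cis from trans regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osncistrans)
```

## The model

Each mature olfactory sensory neuron (OSN) expresses one olfactory receptor
(OR) gene, monoallelically, out of more than a thousand. At the tissue
level this makes the relative abundance of OR transcripts in whole
olfactory mucosa (WOM) RNA-seq a proxy for the relative abundance of OSN
subtypes. The package's pipeline asks, for two strains (here labelled B6
and CAST) and their F1 hybrid: are the strain differences in subtype
abundance driven by cis-acting variation at the OR loci, or by trans-acting
variation in shared machinery?

The discriminating observable is allelic concordance. For gene $g$, let
$y_g$ be the parental log2 fold change (CAST vs B6, after normalization)
and $x_g$ the log2 fold change between the CAST and B6 *alleles* within
the F1. Under cis regulation each allele keeps its parental choice
probability, so $x_g \approx y_g$ (the $x = y$ diagonal); under trans
regulation both alleles share the F1's cellular environment and
$x_g \approx 0$ regardless of $y_g$. Agreement with the diagonal is
quantified by Lin's concordance correlation coefficient

$$\mathrm{ccc} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar{x} - \bar{y})^2},
\qquad \mathrm{ccc} = r \cdot C_b,$$

computed with population ($1/n$) moments so the decomposition into the
Pearson correlation $r$ and the bias-correction factor $C_b$ is exact;
$C_b = 1$ means the best-fit line is exactly $x = y$. Using population
moments is deliberate: with sample moments the identity holds only
approximately.

## Two-stage normalization

Raw counts are first depth-normalized with the median-of-ratios estimator:
the reference for gene $g$ is its geometric mean across samples (genes with
a zero anywhere are excluded), and $s_j$ is the median ratio of sample $j$
to the reference. We rescale the factors to geometric mean one, which makes
the estimator exactly idempotent — re-estimating factors on an already
normalized matrix returns 1 for every sample.

Depth factors cannot correct for how much of the tissue is mature OSNs, so
OR counts are further rescaled by marker-derived OSN-content factors. Five
marker genes stably expressed in mature OSNs (*Omp*, *Adcy3*, *Ano2*,
*Cnga2*, *Gnal*) are first gated: a marker is used only if the rank
correlation between its depth-normalized expression and the per-sample
total of OR counts is at least 0.7. The threshold is a package choice — the
qualitative criterion "strong correlation" must be pinned to be testable —
and it is configurable, as is a Pearson option. Spearman is the default
because rank correlations are the natural choice for this monotone,
heteroskedastic relationship. Constant markers (zero variance, common in
sparse single-cell data) are excluded with a warning rather than an error;
an empty gate is a hard error. The kept markers' geometric mean $g_j$ per
sample yields $f_j = \overline{g}/g_j$, and OR rows (only) are multiplied
by $f_j$. Zeros in kept markers are treated as a data defect (hard error,
naming the sample) because markers are by definition abundant; a
pseudocount option exists for robustness.

## Allelic ratios, filtering and deconvolution

Allele-specific analysis uses only reads overlapping strain-discriminating
SNPs; the input table is assumed pre-filtered upstream (unique mappers, no
reads splicing across the SNP). The per-gene allelic ratio is the allele-1
share of SNP-informative counts, by default pooled across F1 replicates
after per-sample normalization (the same $s_j$ and, by default, $f_j$ are
applied to the SNP counts; a per-sample mode exists because the pooling
convention is a genuine open choice). Genes whose total normalized
informative counts fall at or below the first quartile of that distribution
are dropped — the quartile uses linear interpolation between order
statistics and a strictly-above rule, pinned for reproducibility. Total
normalized expression is then deconvolved as
$(\text{total} \cdot r, \ \text{total} \cdot (1 - r))$. We read the
complement $1 - r$, not the reciprocal $1/r$, as the CAST share: only the
complement conserves the total, which the deconvolution requires.

## In-silico F1 calibration

Allelic fold changes at low informative counts are noisy and slightly
biased. To measure this, an in-silico F1 is built from the parental samples
themselves: each is binomially thinned (count-level thinning is the
count-table equivalent of read subsampling) to half the median F1 library
depth, and paired B6/CAST columns are summed. Its true allelic fold change
equals the parental fold change by construction, so the per-gene deviation
$d_g$ of its allelic estimate from $x = y$ is technical noise; subtracting
$d_g$ from the real F1 estimates yields the corrected fold changes.

Three design choices matter here:

* **Contribution balancing.** Equal *library* depth does not equalize the
  *OSN-derived* contribution of the two parents when their OSN content
  differs; the mismatch shifts every gene's in-silico deviation by a common
  offset that the real F1 does not share, and subtracting it degrades
  $C_b$ wholesale. By default each pair is therefore balanced on its
  observed OR-class totals after depth thinning, honoring the construction's
  premise that each allele contributes half. The depth target is also capped
  at the shallowest parental column so the thinning fraction never exceeds 1.
* **Informative coverage matching.** The in-silico allelic counts have
  informative fraction 1 by construction; they are thinned per gene by the
  informative fraction estimated from the real F1, so the calibration sees
  the same counting noise the real estimates suffer.
* **Averaging draws.** The deviation is the mean over 50 independent
  downsampling draws (log2 scale, consistent with the fold-change axes).
  A single draw's deviation is dominated by its own sampling noise;
  averaging makes the correction's added noise small relative to the bias
  it removes.

With an unbiased generator the deviations are small, so the correction
mainly certifies that technical noise does not masquerade as trans
regulation; on data with systematic per-allele artifacts (mapping bias,
uneven SNP coverage) the deviations are larger and the correction
correspondingly more consequential.

## What the generator emulates — and what it does not

The synthetic-data module produces data with the structure the analysis
assumes, with known ground truth:

* OR-choice probabilities are normalized $\exp(N(0, \sigma^2))$ weights;
  $\sigma = 2$ (default) reproduces the observed skew in which a few
  percent of subtypes carry a quarter of the neurons. The true generative
  law is unknown; the log-normal is a one-parameter modeling choice, not an
  inference.
* Cis effects multiply choice probabilities and the vector is renormalized:
  OR choice is a competition over a fixed OSN pool, so boosting one gene
  dilutes all others.
* F1 allele-choice probabilities: a cis gene's alleles get
  $(p^{B6}_g/2, \ p^{CAST}_g/2)$; a trans gene's alleles are equalized at
  $(p^{B6}_g + p^{CAST}_g)/4$ each; the whole allele vector is
  renormalized. Totals are exact sums of allele counts, and informative
  counts are binomial thinnings with per-gene fraction $\pi_g$.
* Counts are negative-binomial with $\mathrm{var} = \mu + \alpha\mu^2$
  (default $\alpha = 0.05$ for OR genes). Marker genes use a much smaller
  dispersion (0.005): being "stably expressed" is what qualifies them as
  markers, and giving them OR-level biological noise would contradict the
  premise the normalization rests on.
* Per-sample OSN content is uniform on [0.3, 0.9] by default, and both OR
  and marker means scale with it — that shared scaling is the premise of
  the marker normalization.
* A block of non-OSN background genes (default 2000 genes, three times the
  OR-assigned depth in total) does *not* scale with OSN content. Real WOM
  libraries are dominated by non-OSN RNA; without this block the depth
  factors would absorb the OSN-content variation and the two normalization
  stages would not be separable.

Not emulated: read-level artifacts (alignment, positional SNP placement),
reference/mapping bias between alleles, and copy-number variation. Passing
tests on this generator therefore demonstrate that the pipeline's
arithmetic, filters and calibration behave as designed under clean
sampling noise — not that the method is robust to mapping bias, which on
real data is handled upstream (e.g. by pseudo-genomes).

## Numerical and statistical choices

* Hypergeometric upper tails are summed in log space; the enrichment
  p-values this machinery meets in practice reach $10^{-19}$ and must not
  underflow. The tail equals brute-force enumeration exactly (to
  $10^{-12}$) on all instances with $N \le 12$.
* Log2 fold changes use a configurable pseudocount (default 1 on
  doubly-normalized values) since zeros occur at low informative counts.
* The abundance-bias enrichment test dichotomizes the universe at the
  median by default; the split quantile is exposed.
* The differential test is a deliberately lightweight NB Wald test:
  method-of-moments dispersion $\hat\alpha_g = \max(0, (v - m)/m^2)$ pooled
  across groups with df weights, delta-method variance
  $(1/\mu + \hat\alpha)/n$ per group on the log2 ratio, and a $t_{n_A+n_B-2}$
  reference for small-sample calibration (empirical null rate 0.050 at
  6 vs 6). There is no dispersion shrinkage — a documented limitation — and
  the module is an approximation by design, not a replica of a full NB
  GLM framework.
* Degenerate inputs fail loudly and specifically: no usable reference gene
  for depth factors, an empty marker gate, zero marker counts (named
  sample), malformed TSV rows (named line).

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at
1000 OR genes, 3 + 3 parental and 3 F1 replicates, depth $2 \times 10^6$
(seconds per run), 100-replicate null calibrations for the NB test, and
exhaustive hypergeometric enumeration to $N = 12$ — sizes chosen so the
entire suite completes in well under a minute while every moment-based
check retains adequate resolution. All randomness flows from one root seed
through deterministically derived per-stage child seeds
(`child_seed(seed, tag)`), with fixed RNG kinds; reruns are byte-identical,
including every CLI output file.

## Known limitations

* With 3 replicates per strain and NB dispersion $\alpha = 0.05$, the
  parental fold-change noise floor is
  $2(\alpha/3)/\ln(2)^2 \approx 0.07$ log2² regardless of depth, which
  bounds the achievable ccc near 0.95 even with noiseless allelic
  estimates; with a heavy-tailed repertoire the observed ceiling is lower
  (≈ 0.87–0.90 at the default study conditions). Deeper replication, not
  deeper sequencing, is what would raise it.
* Likewise, no per-sample factor can remove per-gene NB noise: after
  two-stage normalization a constant gene's cross-sample CV converges to
  $\sqrt{\alpha + \alpha_{\text{marker}}/k}$, about 10% at $\alpha = 0.01$,
  not to zero.
* The in-silico calibration measures noise reproducible by downsampling;
  artifacts that differ between the real F1 and the parents (e.g.
  F1-specific library chemistry) are invisible to it.
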