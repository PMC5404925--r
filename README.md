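# osncistrans

Quantifying olfactory-sensory-neuron (OSN) subtype repertoires from RNA-seq
counts of olfactory receptor (OR) genes, and deciding whether repertoire
differences between mouse strains are **cis**- or **trans**-regulated from
allelic concordance in F1 hybrids.

## The problem

Each mature OSN expresses a single OR gene, so the relative abundance of OR
transcripts in whole olfactory mucosa (WOM) RNA-seq is a proxy for the
relative number of OSNs of each subtype. Comparing repertoires across
strains requires two normalizations: sequencing depth, and the fraction of
the tissue that is mature OSNs. Whether a strain difference in a subtype's
abundance is caused by variation acting on the OR locus itself (cis) or on
shared machinery (trans) can be read off an F1 hybrid: under cis
regulation, the F1's B6-allele repertoire should match the B6 parent and
its CAST-allele repertoire the CAST parent, so per-gene allelic log2 fold
changes should equal parental log2 fold changes (the x = y line). Under
trans regulation both alleles see the same cellular environment and the
allelic fold changes collapse to zero.

The package implements:

* **Two-stage normalization** — median-of-ratios depth size factors
  `s_j`, then OSN-content factors `f_j = mean(g)/g_j` from the geometric
  mean `g_j` of mature-OSN marker genes (*Omp*, *Adcy3*, *Ano2*, *Cnga2*,
  *Gnal*), gated on their rank correlation with total OR counts.
* **Allelic analysis** — per-gene allelic ratio
  `r = allele1/(allele1 + allele2)` from SNP-informative counts, a
  lowest-quartile informative-count filter, and deconvolution of total
  expression into allele-specific values `(total * r, total * (1 - r))`.
* **In-silico F1 calibration** — parental samples binomially thinned to
  half the median F1 depth and combined pairwise into a synthetic hybrid
  whose true allelic fold change equals the parental fold change; the
  per-gene deviation `d_g` of its allelic estimates from x = y measures
  technical noise and is subtracted from the real F1 estimates.
* **Concordance statistics** — Lin's concordance correlation coefficient
  `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with its exact
  decomposition `ccc = r * C_b`, where `C_b = 1` means the best fit is
  exactly the diagonal.
* **Statistical primitives** — exact log-space hypergeometric upper tails,
  Benjamini-Hochberg adjustment, `RQ = 2^dCt` for qPCR, and a lightweight
  negative-binomial Wald test applying the adjusted-p `<= 0.05` calling
  rule (a stand-in for a full empirical-Bayes NB fit, not a replica).
* **A synthetic-data generator** with known ground truth: log-normal
  OR-choice probabilities (a few subtypes dominate the repertoire),
  multiplicative cis effects, cis/trans F1 allele-choice models, per-gene
  SNP-informative fractions, marker genes tracking per-sample OSN content,
  a non-OSN background block, and NB sequencing noise.

## Worked example

```r
library(osncistrans)

ds <- simulate_cistrans_dataset("cis", n_genes = 1000, n_parental = 3,
                                n_f1 = 3, depth = 2e6, seed = 1)
report <- run_cistrans(ds$b6, ds$cast, ds$f1_total, ds$f1_allelic, seed = 1)
report
#> cis/trans concordance report
#>   genes: 1000 total OR, 989 with allelic ratio, 750 informative
#>   raw:       ccc = 0.8698, C_b = 0.9987, r = 0.8709, slope = 0.914
#>   corrected: ccc = 0.8709, C_b = 0.9986, r = 0.8721, slope = 0.917
```

989 of 1000 OR genes had at least one SNP-informative read; 750 survive the
lowest-quartile filter. Their allelic fold changes agree with the parental
fold changes with `ccc = 0.87` and a bias-correction factor `C_b = 0.999`:
the cloud sits on the x = y diagonal, the cis signature. On a trans-mode
dataset the same call returns `ccc ≈ 0.00` and a regression slope of
allelic on parental fold changes `≈ 0.00`: parental differences are real
but are not inherited by the alleles.

The same analyses are scriptable from a shell:

```sh
Rscript inst/scripts/osncistrans.R simulate --config cfg.json --outdir sim --seed 1
Rscript inst/scripts/osncistrans.R cistrans --b6 sim/b6_counts.tsv \
    --cast sim/cast_counts.tsv --f1 sim/f1_counts.tsv \
    --allelic sim/f1_allelic.tsv --out results --seed 1
```

All commands are byte-reproducible under a fixed seed and configuration.

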