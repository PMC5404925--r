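Package: osncistrans
Title: Olfactory Receptor Repertoire Quantification and Cis/Trans Inference
    from F1 Allelic Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies olfactory-sensory-neuron (OSN) subtype repertoires
    from olfactory receptor (OR) gene count tables and tests whether
    repertoire differences between mouse strains are cis- or trans-regulated
    using allelic concordance in F1 hybrids.  Provides two-stage
    normalization (median-of-ratios sequencing depth, then OSN content via
    mature-OSN marker genes), SNP-informative allelic ratio estimation and
    deconvolution, an in-silico F1 built by binomial downsampling of parental
    samples to calibrate technical noise in allelic fold changes, Lin's
    concordance correlation coefficient with its bias-correction factor,
    exact hypergeometric enrichment tests, a lightweight negative-binomial
    differential-abundance test, and a synthetic count-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
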