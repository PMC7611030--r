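Package: fetalcall
Title: Noninvasive Fetal Genotyping of Maternal Variants from Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint Bayesian inference of fetal genotype and fetal fraction from
    droplet digital PCR (ddPCR) counts on maternal plasma cell-free DNA.
    Implements Poisson partition statistics for droplet counts (replicate-well
    merging, concentration estimates with 95% confidence intervals, fractional
    allele abundance), fetal-fraction estimation from a paternal-allele assay
    with sample-level quality gates, a binomial latent-genotype model with both
    a Metropolis-within-Gibbs MCMC sampler and a deterministic quadrature
    engine, allelic-bias calibration from genomic DNA controls, a copy-number
    (deletion) assay mode, clinical per-sample and per-pregnancy calling with
    follow-up-sample logic, cohort-level sensitivity and specificity summaries,
    and a droplet-count simulator for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rjags,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
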