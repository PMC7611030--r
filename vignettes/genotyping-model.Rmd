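---
title: "Bayesian noninvasive fetal genotyping from ddPCR: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian noninvasive fetal genotyping from ddPCR: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalcall)
```

## The inference problem

A pregnant woman heterozygous for a pathogenic variant contributes a 50:50
mixture of reference and variant alleles to her plasma cell-free DNA. The
fetal (placental) contribution, a fraction $f$ of the total cfDNA, shifts
that balance only if the fetal genotype differs from the mother's: a
heterozygous fetus leaves the balance at 50:50, while a
homozygous-reference fetus raises the expected reference-allele share to

$$\theta_0(f) = \tfrac12 + \tfrac{f}{2},$$

i.e. 55:45 at $f = 0.10$. The genotype signal therefore scales with $f$,
and $f$ itself must be measured — here from a second ddPCR assay that
counts a paternal-only allele (an opposite-homozygote SNP, or *ZFY* when
the fetus is known male) against a maternally shared allele. Because the
mother contributes two copies of the shared target per genome and the
fetus one shared plus one paternal-only copy, the paternal channel carries
a share $f/2$ of that assay's concentration, giving the point estimator
$\hat f = 2\lambda_{pat}/(\lambda_{pat}+\lambda_{mat})$. The same counting
argument covers both assay designs, which is why the package implements a
single formula.

## Data-generating model

ddPCR partitions a reaction into $n$ droplets of volume $v$; a target at
concentration $\lambda$ (copies/µL) leaves a droplet empty with
probability $e^{-\lambda v}$, so the positive count is

$$k \sim \mathrm{Binomial}\!\left(n,\; 1 - e^{-\lambda v}\right).$$

We use this exact binomial partition form rather than its Poisson
approximation; at ddPCR counts the difference is small, but the binomial
costs nothing. A sample contributes four channels:

| channel | rate |
|---|---|
| reference allele | $c_{var}\,\theta(f,g)$ |
| variant allele | $c_{var}\,(1-\theta(f,g))$ |
| paternal-only allele | $c_{ff}\, f/2$ |
| maternally shared allele | $c_{ff}\,(1 - f/2)$ |

with latent genotype $g \in \{\text{HOM\_REF}, \text{HET}\}$ and assay
totals $c_{var}, c_{ff}$. An assay-specific bias factor $b$ (measured on a
heterozygous maternal gDNA control as the ratio of channel concentrations,
`calibrate_bias()`) tilts the observed fraction to
$\theta = b\theta_0/(b\theta_0 + 1 - \theta_0)$; almost all assays sit at
$b \approx 1$, but the correction matters for the occasional probe with a
reference-allele preference.

For maternal deletions, where no variant probe exists, the copy-number
mode compares a target amplicon inside the deleted interval with a
two-copy reference locus: the expected concentration ratio is
$\tfrac12 + \tfrac f2$ for a homozygous-reference fetus and exactly
$\tfrac12$ when the fetus inherited the deletion. We parameterize the
likelihood by the reference-locus concentration, with the target channel
at that concentration times the expected ratio, so the assay total is not
double-counted.

### Priors

The reference analysis specifies only that priors are vague; the package's
choices, all overridable in `model_config()`, are

* $f \sim \mathrm{Uniform}(0, 0.5)$ — clinical fetal fractions rarely
  exceed 0.3, and the bound keeps $\theta \le 0.75$;
* $c_{var}, c_{ff} \sim \mathrm{Uniform}(0, 5\hat\lambda)$ with
  $\hat\lambda$ the point-estimate concentration from the sample's own
  merged counts (floored at one droplet equivalent so zero-count data
  still yield a proper prior). At ddPCR depths the posterior is orders of
  magnitude narrower than this bound, making the analysis effectively
  scale-free;
* $\Pr(g = \text{HOM\_REF}) = 0.5$ — Mendelian segregation from a
  heterozygous mother.

Tests verify that on well-powered samples the call probability moves by
less than 0.01 when the $f$ bound or the concentration-bound multiplier is
changed, and that with the fetal-fraction prior collapsed to $f = 0$ the
posterior returns the genotype prior exactly (the identifiability limit:
without fetal signal the data cannot distinguish genotypes).

## Two inference engines

`run_mcmc()` is a Metropolis-within-Gibbs sampler (compiled, Rcpp):
Gaussian random walks on $\mathrm{logit}(f/f_{max})$ and the
log-concentrations, with step sizes adapted toward 40% acceptance during
the adaptation phase only (so the post-adaptation chain is a valid
time-homogeneous Markov chain), and an exact Gibbs draw of the binary
genotype from its full conditional every sweep. The default schedule is 4
chains × (1000 adaptation + 10 000 burn-in + 50 000 sampling) iterations,
retaining 200 000 draws. A single integer seed fans out deterministically
to per-chain RNG streams. Split-$\hat R$ and a Geyer-truncated bulk ESS
are computed per continuous parameter; any $\hat R > 1.05$ flags the
result as non-converged (with a warning) rather than silently returning.

`quadrature_posterior()` evaluates the same posterior deterministically.
Given $f$ and $g$ the two assays factorize, so each concentration
integrates out in one dimension; the genotype marginal likelihoods are
then one-dimensional integrals over $f$:

$$m_g = \int p(f) \left[\int p(c_{var})\,L_{var}(c_{var}; f, g)\,
  dc_{var}\right]\left[\int p(c_{ff})\,L_{ff}(c_{ff}; f)\,dc_{ff}\right] df.$$

Trapezoid rules are used on a 201-point $f$ grid and 257-point
concentration grids. Because a uniform prior is flat, the concentration
grids cover only the window $\hat\lambda \pm 12$ standard errors
(intersected with the prior support) — outside it the likelihood is
negligible — which keeps the grid fine where the posterior lives even for
deeply covered samples. All accumulation is in log space (log-sum-exp);
an underflow of both genotype marginals is an error, never a silent zero.
The genotype Gibbs step in the sampler cannot mode-stick (the genotype is
re-drawn exactly each sweep), and the quadrature engine guards the sampler
in tests: the two agree within 0.02 in $p_{hom}$ across a 20-sample panel
spanning $f \in [0.02, 0.25]$, and on one fixture both agree with an
independent JAGS fit of the identical model to three decimals.

## Droplet statistics

Concentrations are estimated as $\hat\lambda = -\ln(1 - k/n)/v$.
Confidence intervals transform a Wilson 95% score interval on $k/n$
through the same monotone map; the exact interval construction used by
instrument software is proprietary, and the Wilson-based choice is
reproducible and may differ from instrument output in the third decimal.
For fractional abundance and fetal fraction, intervals are propagated by
evaluating the ratio at paired interval extremes — a deliberately
conservative (slightly wide) interval. Replicate wells (up to 16 per
assay) are merged by summing counts; droplets are independent partitions,
so pooling is exact, and a variance-ratio test in the suite checks the
simulator respects that independence.

Degenerate inputs are handled at the edges, not inside the likelihood: a
saturated channel ($k = n$) is a hard error (the concentration is
unbounded, the sample is unquantifiable, and clipping would fake
precision); $k = 0$ gives $\hat\lambda = 0$ with a one-sided interval;
both channels zero makes a fraction undefined (error). No-template
controls fail the run on any positive droplet by default
(`max_positive = 0`); the threshold is configurable because single-droplet
artifacts are common in practice.

## QC gates and calling

Sample exclusion happens before modeling, on the point estimate $\hat f$:
fetal fraction below 2% or fewer than 10 paternal-allele positive
droplets fails the sample (`LOW_FETAL_FRACTION`, `LOW_PATERNAL_DROPLETS`),
as does a contaminated NTC. A QC-failed sample is never called, whatever
its posterior. Calls use inclusive thresholds — $p_{hom} \ge 0.95$ calls
HOM_REF, $p_{hom} \le 0.05$ calls HET — treating the endpoints as
conclusive (the boundary convention is ambiguous in common usage;
landing exactly on 0.95/0.05 is measure-zero for the MCMC engine anyway).
Within a pregnancy, samples are walked in gestational order (missing ages
sort last, with a warning); the first conclusive call is final, QC
failures and intermediate probabilities hand over to the next (follow-up)
sample, and a pregnancy with no conclusive sample is UNRESOLVED.
Conflicting conclusive calls within one pregnancy are treated as an error
by `evaluate_pregnancy()` — inter-sample concordance is the expectation,
so a conflict means an upstream problem — while the batch pipeline
catches it and reports the pregnancy UNRESOLVED with reason
`CONFLICTING_CALLS` instead of aborting the run.

Cohort "clinical sensitivity" is diagnostic yield times correctness
(conclusive correct calls over all pregnancies) and "specificity" is the
fraction of conclusive calls that are correct; the raw confusion table is
returned so users preferring per-class definitions can compute them.

## What the simulator does and does not emulate

`simulate_sample()` inverts the likelihood exactly: channel rates are
derived from truth via the same maps the model uses, and droplet counts
are drawn at the partition level, $\mathrm{Binomial}(n, 1-e^{-\lambda v})$
per channel — distributionally identical to seeding Poisson molecule
counts per droplet, but without per-droplet bookkeeping. Defaults are a
realistic operating point chosen once: 0.85 nL droplets (a common
instrument's nominal volume; the analysis never depends on it except as a
units convention), 15 000 accepted droplets/well, 4 wells/assay, 50
copies/µL per assay; cohort fetal fractions are drawn uniformly from
2.5%–26.1%, the observed envelope of callable clinical samples.

The simulator does **not** model fluorescence amplitudes, "rain",
droplet-volume variability, inter-well concentration drift, maternal-cell
contamination, or gestational-age dynamics of fetal fraction. Passing
tests therefore demonstrate correctness of the inference given the
partition model — self-consistency, calibration, coverage and
engine agreement — not robustness to instrument-level artifacts, which
enter real data upstream of the counts this package consumes.

## Validation performed by the suite

All tests generate their data in code under fixed seeds; problem sizes are
chosen so the full suite runs in about two minutes on one core while
keeping Monte Carlo error well inside the asserted tolerances:

* closed-form oracles for concentration, fractional abundance, fetal
  fraction and bias (independent hand evaluations frozen into the tests);
* MCMC vs quadrature agreement ($\le 0.02$) on a 20-sample panel at the
  full default schedule; a JAGS cross-check on one fixture;
* zero discordant conclusive calls on 200 simulated pregnancies with
  $f \ge 5\%$ and 105 000 droplets per assay (7 wells × 15 000);
* posterior calibration on 400 prior-drawn simulations (χ² at α = 0.01)
  and ≥ 90% coverage of the true $f$ by the 95% credible interval over
  200 simulations;
* QC-gate and threshold fixtures, including boundary values.

## Known limitations

* Single-fetus pregnancies only; twins violate the one-genotype model.
* Maternally inherited SNVs/small indels and maternal deletions are
  covered; paternal-variant detection and relative haplotype dosage are
  different problems with different likelihoods.
* The model consumes instrument-called droplet counts; thresholding of
  raw fluorescence is upstream and out of scope.
* Calibration guarantees hold under the partition model; heavy
  contamination or assay bias beyond the single multiplicative factor
  would need additional modeling.
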