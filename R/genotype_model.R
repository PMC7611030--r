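#' A plasma sample's paired ddPCR observations
#'
#' Bundles the merged droplet counts of a sample's two assays: the variant
#' assay (reference vs variant allele, or in copy-number mode target vs
#' reference locus) and the fetal-fraction assay (paternal-only vs
#' maternally shared allele).
#'
#' @param sample_id,pregnancy_id Identifiers (pregnancy defaults to sample).
#' @param variant_assay For `assay_mode = "ALLELIC"` a list
#'   `list(ref = , var = )` of [channel_counts]; for `"CNV_DELETION"` a list
#'   `list(target = , ref_locus = )`.
#' @param ff_assay An [ff_assay_observation].
#' @param droplet_volume Droplet volume in microliters.
#' @param assay_mode `"ALLELIC"` (allelic-balance SNV/indel assay) or
#'   `"CNV_DELETION"` (copy-number assay for maternal deletions).
#' @param gestation_weeks Optional gestational age of the draw.
#' @return An object of class `sample_observation`.
#' @export
sample_observation <- function(sample_id, variant_assay, ff_assay,
                               pregnancy_id = sample_id,
                               droplet_volume = 8.5e-4,
                               assay_mode = c("ALLELIC", "CNV_DELETION"),
                               gestation_weeks = NA_real_) {
  assay_mode <- match.arg(assay_mode)
  want <- if (assay_mode == "ALLELIC") c("ref", "var") else c("target", "ref_locus")
  if (!is.list(variant_assay) || !all(want %in% names(variant_assay)))
    stop("variant_assay must be a named list with elements ",
         paste(want, collapse = ", "), " for assay_mode ", assay_mode)
  for (nm in want) stopifnot(inherits(variant_assay[[nm]], "channel_counts"))
  stopifnot(inherits(ff_assay, "ff_assay_observation"), droplet_volume > 0)
  structure(list(sample_id = sample_id, pregnancy_id = pregnancy_id,
                 variant_assay = variant_assay[want], ff_assay = ff_assay,
                 droplet_volume = droplet_volume, assay_mode = assay_mode,
                 gestation_weeks = gestation_weeks),
            class = "sample_observation")
}

#' Model configuration: priors and bias
#'
#' Vague priors for the joint genotype/fetal-fraction model. The fetal
#' fraction takes a Uniform(0, `f_max`) prior (default upper bound 0.5,
#' comfortably above fetal fractions seen in maternal plasma); each assay's
#' total concentration takes a Uniform(0, `conc_max`) prior whose bound
#' defaults to `conc_max_mult` (5) times the point-estimate concentration
#' from the data, which is effectively scale-free at ddPCR droplet counts.
#' The genotype prior is 0.5/0.5, Mendelian segregation from a heterozygous
#' mother.
#'
#' @param f_max Upper bound of the uniform fetal-fraction prior; `0` pins
#'   the fetal fraction at zero (useful to probe the identifiability limit).
#' @param genotype_prior Prior probability that the fetus is homozygous
#'   reference, in (0, 1).
#' @param bias Reference-allele bias factor for the variant assay (1 =
#'   unbiased; see [calibrate_bias()]).
#' @param conc_max_var,conc_max_ff Explicit upper bounds (copies/uL) for the
#'   concentration priors; `NULL` derives them from the data.
#' @param conc_max_mult Multiplier for the data-derived bounds.
#' @return An object of class `model_config`.
#' @export
model_config <- function(f_max = 0.5, genotype_prior = 0.5, bias = 1,
                         conc_max_var = NULL, conc_max_ff = NULL,
                         conc_max_mult = 5) {
  stopifnot(f_max >= 0, f_max <= 1, genotype_prior > 0, genotype_prior < 1,
            bias > 0, conc_max_mult > 1)
  structure(list(f_max = f_max, genotype_prior = genotype_prior, bias = bias,
                 conc_max_var = conc_max_var, conc_max_ff = conc_max_ff,
                 conc_max_mult = conc_max_mult),
            class = "model_config")
}

#' MCMC schedule
#'
#' Defaults follow the reference schedule: 4 chains, a 1000-iteration
#' adaptation phase, 10 000-iteration burn-in and 50 000 sampling
#' iterations, for 200 000 retained draws across the chains.
#'
#' @param chains Number of chains.
#' @param adapt_iters Step-size adaptation iterations (discarded).
#' @param burn_in Burn-in iterations (discarded).
#' @param sampling_iters Retained iterations per chain.
#' @param seed Integer seed; fans out deterministically to per-chain streams.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, adapt_iters = 1000L, burn_in = 10000L,
                        sampling_iters = 50000L, seed = 1L) {
  stopifnot(chains >= 1, adapt_iters >= 1, burn_in >= 1, sampling_iters >= 1)
  structure(list(chains = as.integer(chains),
                 adapt_iters = as.integer(adapt_iters),
                 burn_in = as.integer(burn_in),
                 sampling_iters = as.integer(sampling_iters),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

.norm_genotype <- function(genotype) {
  if (genotype %in% c("HET", "HET_DELETION")) "HET"
  else if (genotype == "HOM_REF") "HOM_REF"
  else stop("genotype must be HOM_REF, HET or HET_DELETION, got ", genotype)
}

#' Expected reference-allele fraction in cfDNA
#'
#' For a mother heterozygous for the variant, cfDNA from a heterozygous
#' fetus keeps the 50:50 allelic balance, while a homozygous-reference fetus
#' overrepresents the reference allele by half its fetal fraction:
#' `theta0 = 0.5 + f/2`. At fetal fraction 10% this is the familiar 55:45
#' ratio. An assay-specific bias factor `b` tilts the observed fraction to
#' `b*theta0 / (b*theta0 + (1 - theta0))`.
#'
#' @param genotype `"HOM_REF"` or `"HET"`.
#' @param f Fetal fraction in `[0, 1]`.
#' @param bias Reference-allele bias factor (> 0).
#' @return Expected reference-channel fraction in `[0, 1]`.
#' @examples
#' expected_ref_fraction("HOM_REF", 0.10)  # 0.55
#' expected_ref_fraction("HET", 0.10)      # 0.50
#' @export
expected_ref_fraction <- function(genotype, f, bias = 1) {
  genotype <- .norm_genotype(genotype)
  if (any(f < 0) || any(f > 1)) stop("fetal fraction f must lie in [0, 1]")
  if (bias <= 0) stop("bias must be > 0")
  theta0 <- if (genotype == "HOM_REF") 0.5 + f / 2 else rep(0.5, length(f))
  bias * theta0 / (bias * theta0 + (1 - theta0))
}

#' Expected target/reference-locus concentration ratio (deletion mode)
#'
#' For a mother heterozygous for a deletion, the target amplicon sits on one
#' maternal copy. Per genome the mother contributes 1 target copy and the
#' fetus 2 (homozygous reference) or 1 (inherited the deletion) against a
#' 2-copy reference locus, so the expected concentration ratio is
#' `0.5 + f/2` or `0.5` respectively.
#'
#' @param genotype `"HOM_REF"` or `"HET_DELETION"` (alias `"HET"`).
#' @param f Fetal fraction in `[0, 1]`.
#' @return Expected target:reference-locus concentration ratio.
#' @examples
#' expected_cnv_ratio("HOM_REF", 0.2)       # 0.6
#' expected_cnv_ratio("HET_DELETION", 0.2)  # 0.5
#' @export
expected_cnv_ratio <- function(genotype, f) {
  genotype <- .norm_genotype(genotype)
  if (any(f < 0) || any(f > 1)) stop("fetal fraction f must lie in [0, 1]")
  if (genotype == "HOM_REF") 0.5 + f / 2 else rep(0.5, length(f))
}

# counts of the four channels in sampler order:
# (ref|target, var|ref_locus, paternal, maternal)
.obs_counts <- function(obs) {
  va <- obs$variant_assay
  list(k = c(va[[1]]$k, va[[2]]$k,
             obs$ff_assay$paternal_channel$k, obs$ff_assay$maternal_channel$k),
       n = c(va[[1]]$n, va[[2]]$n,
             obs$ff_assay$paternal_channel$n, obs$ff_assay$maternal_channel$n))
}

# per-channel Poisson rates under the data-generating process
.channel_lambdas <- function(obs, genotype, f, conc_var, conc_ff, bias = 1) {
  if (obs$assay_mode == "CNV_DELETION") {
    r <- expected_cnv_ratio(genotype, f)
    lam12 <- c(conc_var * r, conc_var)
  } else {
    th <- expected_ref_fraction(genotype, f, bias)
    lam12 <- c(conc_var * th, conc_var * (1 - th))
  }
  c(lam12, conc_ff * f / 2, conc_ff * (1 - f / 2))
}

#' Joint log-likelihood of a sample's droplet counts
#'
#' Sum over the four channels of `Binomial(k | n, 1 - exp(-lambda * v))`
#' log-mass, with channel rates derived from the latent genotype, fetal
#' fraction `f` and the two assay concentrations. Parameters outside the
#' prior support return `-Inf` (rejection semantics), not an error.
#'
#' @param obs A [sample_observation].
#' @param genotype `"HOM_REF"`, `"HET"` or (CNV mode) `"HET_DELETION"`.
#' @param f Fetal fraction.
#' @param conc_var Variant-assay total concentration (copies/uL); in CNV
#'   mode the reference-locus concentration.
#' @param conc_ff Fetal-fraction-assay total concentration (copies/uL).
#' @param cfg A [model_config] (supplies bias and prior support).
#' @return Log-likelihood (scalar; `-Inf` outside support).
#' @export
log_likelihood <- function(obs, genotype, f, conc_var, conc_ff,
                           cfg = model_config()) {
  stopifnot(inherits(obs, "sample_observation"))
  genotype <- .norm_genotype(genotype)
  sup <- .conc_bounds(obs, cfg)
  if (is.na(f) || f < 0 || f > max(cfg$f_max, 0) ||
      conc_var < 0 || conc_var > sup$var ||
      conc_ff < 0 || conc_ff > sup$ff) return(-Inf)
  lam <- .channel_lambdas(obs, genotype, f, conc_var, conc_ff, cfg$bias)
  cnt <- .obs_counts(obs)
  p <- -expm1(-lam * obs$droplet_volume)
  sum(stats::dbinom(cnt$k, cnt$n, pmin(pmax(p, 0), 1), log = TRUE))
}

# data-derived upper bounds of the uniform concentration priors
.conc_bounds <- function(obs, cfg) {
  cnt <- .obs_counts(obs)
  v <- obs$droplet_volume
  lam_hat <- -log1p(-pmin(cnt$k / cnt$n, 1 - 1 / cnt$n)) / v
  # floor of one droplet equivalent keeps the bound positive at zero counts
  floor1 <- 1 / (min(cnt$n) * v)
  var_hat <- if (obs$assay_mode == "CNV_DELETION") lam_hat[2]
             else lam_hat[1] + lam_hat[2]
  ff_hat <- lam_hat[3] + lam_hat[4]
  list(var = if (!is.null(cfg$conc_max_var)) cfg$conc_max_var
             else cfg$conc_max_mult * max(var_hat, floor1),
       ff = if (!is.null(cfg$conc_max_ff)) cfg$conc_max_ff
            else cfg$conc_max_mult * max(ff_hat, floor1))
}

# integration window for a concentration parameter: wide enough to contain
# all non-negligible likelihood (+-12 sd around the point estimate),
# intersected with the prior support
.conc_grid <- function(c_hat, k_tot, n_min, v, c_max, n_points) {
  half <- 12 * (sqrt(k_tot) + 3) / (n_min * v)
  lo <- max(0, c_hat - half)
  hi <- min(c_max, c_hat + half)
  if (hi <= lo) { lo <- 0; hi <- c_max }
  seq(lo, hi, length.out = n_points)
}

# trapezoid weights for a uniform grid
.trap_w <- function(x) {
  nw <- length(x)
  w <- rep(diff(x)[1], nw); w[c(1, nw)] <- w[1] / 2
  w
}

# log(sum(w * exp(x))) computed stably
.wlse <- function(x, w) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(w * exp(x - m)))
}

# quantiles of a density known on a grid (linear interpolation of the CDF)
.grid_quantiles <- function(x, log_dens, probs = c(0.5, 0.025, 0.975)) {
  if (length(x) == 1L) return(stats::setNames(rep(x, length(probs)),
                                              c("median", "lower", "upper")))
  m <- max(log_dens)
  d <- exp(log_dens - m) * .trap_w(x)
  cdf <- cumsum(d) / sum(d)
  q <- stats::approx(cdf, x, xout = probs, yleft = x[1], yright = x[length(x)],
                     ties = "ordered")$y
  stats::setNames(q, c("median", "lower", "upper"))
}

.posterior_summary <- function(p_hom, f_post, conc_var_post, conc_ff_post,
                               engine, total_samples = NA_integer_,
                               diagnostics = NULL, converged = NA,
                               draws = NULL) {
  structure(list(p_hom = p_hom, f_post = f_post,
                 conc_var_post = conc_var_post, conc_ff_post = conc_ff_post,
                 engine = engine, total_samples = total_samples,
                 diagnostics = diagnostics, converged = converged,
                 draws = draws),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> [%s] P(fetus HOM_REF) = %.4f\n",
              x$engine, x$p_hom))
  cat(sprintf("  fetal fraction: %.4f (95%% CrI %.4f-%.4f)\n",
              x$f_post[["median"]], x$f_post[["lower"]], x$f_post[["upper"]]))
  if (!is.na(x$total_samples))
    cat(sprintf("  %d retained posterior samples; converged: %s\n",
                x$total_samples, as.character(x$converged)))
  invisible(x)
}

#' Deterministic posterior by nested quadrature
#'
#' Exact (to grid resolution) evaluation of the same posterior the MCMC
#' sampler targets, used as a reference engine. Given the fetal fraction and
#' genotype the two assays factorize, so each assay concentration integrates
#' out in one dimension; the genotype marginal likelihoods then come from a
#' one-dimensional integral over the fetal fraction. All accumulation is in
#' log space.
#'
#' @param obs A [sample_observation].
#' @param cfg A [model_config].
#' @param grid List with `n_f` and `n_conc` grid resolutions (each >= 64;
#'   defaults 201 and 257).
#' @return A `posterior_summary` with `engine = "QUADRATURE"` and
#'   `p_hom`, `f_post` and per-assay concentration posteriors.
#' @export
quadrature_posterior <- function(obs, cfg = model_config(),
                                 grid = list(n_f = 201L, n_conc = 257L)) {
  stopifnot(inherits(obs, "sample_observation"))
  if (is.null(grid$n_f)) grid$n_f <- 201L
  if (is.null(grid$n_conc)) grid$n_conc <- 257L
  if (cfg$f_max > 0 && grid$n_f < 64) stop("grid$n_f must be >= 64")
  if (grid$n_conc < 64) stop("grid$n_conc must be >= 64")
  cnt <- .obs_counts(obs)
  v <- obs$droplet_volume
  sup <- .conc_bounds(obs, cfg)

  fs <- if (cfg$f_max > 0) seq(0, cfg$f_max, length.out = grid$n_f) else 0
  wf <- if (length(fs) > 1) .trap_w(fs) else 1

  lam_hat <- -log1p(-pmin(cnt$k / cnt$n, 1 - 1 / cnt$n)) / v
  cvh <- if (obs$assay_mode == "CNV_DELETION") lam_hat[2] else lam_hat[1] + lam_hat[2]
  cgrid_var <- .conc_grid(cvh, cnt$k[1] + cnt$k[2], min(cnt$n[1:2]), v,
                          sup$var, grid$n_conc)
  cgrid_ff <- .conc_grid(lam_hat[3] + lam_hat[4], cnt$k[3] + cnt$k[4],
                         min(cnt$n[3:4]), v, sup$ff, grid$n_conc)
  wcv <- .trap_w(cgrid_var); wcf <- .trap_w(cgrid_ff)

  ll_mat <- function(k1, n1, lam1, k2, n2, lam2) {
    stats::dbinom(k1, n1, -expm1(-lam1 * v), log = TRUE) +
      stats::dbinom(k2, n2, -expm1(-lam2 * v), log = TRUE)
  }
  # variant assay: nf x nc log-likelihood matrix per genotype
  var_mat <- function(genotype) {
    if (obs$assay_mode == "CNV_DELETION") {
      r <- expected_cnv_ratio(genotype, fs)
      ll_mat(cnt$k[1], cnt$n[1], outer(r, cgrid_var),
             cnt$k[2], cnt$n[2], outer(rep(1, length(fs)), cgrid_var))
    } else {
      th <- expected_ref_fraction(genotype, fs, cfg$bias)
      ll_mat(cnt$k[1], cnt$n[1], outer(th, cgrid_var),
             cnt$k[2], cnt$n[2], outer(1 - th, cgrid_var))
    }
  }
  M_hom <- var_mat("HOM_REF"); M_het <- var_mat("HET")
  M_ff <- ll_mat(cnt$k[3], cnt$n[3], outer(fs / 2, cgrid_ff),
                 cnt$k[4], cnt$n[4], outer(1 - fs / 2, cgrid_ff))
  M_hom <- matrix(M_hom, length(fs)); M_het <- matrix(M_het, length(fs))
  M_ff <- matrix(M_ff, length(fs))

  inner <- function(M, w) apply(M, 1, .wlse, w = w)   # integrate out conc
  iv_hom <- inner(M_hom, wcv); iv_het <- inner(M_het, wcv)
  iff <- inner(M_ff, wcf)

  lp_hom <- iv_hom + iff   # log integrand over f, per genotype
  lp_het <- iv_het + iff
  lm_hom <- .wlse(lp_hom, wf); lm_het <- .wlse(lp_het, wf)
  if (!is.finite(lm_hom) && !is.finite(lm_het))
    stop("marginal likelihood underflowed for both genotypes; check inputs")
  lo <- log(cfg$genotype_prior) + lm_hom -
        (log1p(-cfg$genotype_prior) + lm_het)
  p_hom <- 1 / (1 + exp(-lo))

  # fetal-fraction posterior: genotype mixture on the f grid
  mix_f <- mapply(function(a, b) .wlse(c(a, b), c(cfg$genotype_prior,
                                                  1 - cfg$genotype_prior)),
                  lp_hom, lp_het)
  f_post <- .grid_quantiles(fs, mix_f)

  # concentration posteriors: mix over f (and genotype for the variant assay)
  wlog <- log(wf)
  col_lse <- function(M, add) apply(M + add, 2, function(col) .wlse(col, rep(1, length(col))))
  d_var <- mapply(function(a, b) .wlse(c(a, b), c(cfg$genotype_prior,
                                                  1 - cfg$genotype_prior)),
                  col_lse(M_hom, iff + wlog), col_lse(M_het, iff + wlog))
  mix_iv <- mapply(function(a, b) .wlse(c(a, b), c(cfg$genotype_prior,
                                                   1 - cfg$genotype_prior)),
                   iv_hom, iv_het)
  d_ff <- col_lse(M_ff, mix_iv + wlog)

  .posterior_summary(p_hom = p_hom, f_post = f_post,
                     conc_var_post = .grid_quantiles(cgrid_var, d_var),
                     conc_ff_post = .grid_quantiles(cgrid_ff, d_ff),
                     engine = "QUADRATURE")
}

#' Sample the joint posterior by Metropolis-within-Gibbs MCMC
#'
#' Gaussian random walks on the logit fetal fraction and log concentrations
#' (step sizes adapted toward 40% acceptance during the adaptation phase
#' only) with an exact Gibbs draw of the binary fetal genotype from its full
#' conditional each sweep. `p_hom` is the posterior frequency of the
#' homozygous-reference genotype across all retained draws.
#'
#' @param obs A [sample_observation].
#' @param cfg A [model_config].
#' @param mcmc An [mcmc_config]; the seed fans out deterministically to
#'   per-chain RNG streams.
#' @param keep_draws Keep per-chain draw matrices in the result (default
#'   `TRUE`; needed for [export_draws()] and trace plotting).
#' @return A `posterior_summary` with `engine = "MCMC"`, convergence
#'   diagnostics (split R-hat and bulk ESS per continuous parameter) and
#'   `total_samples = chains * sampling_iters`. If any R-hat exceeds 1.05
#'   the result is flagged `converged = FALSE` (with a warning), never
#'   silently returned as converged.
#' @export
run_mcmc <- function(obs, cfg = model_config(), mcmc = mcmc_config(),
                     keep_draws = TRUE) {
  stopifnot(inherits(obs, "sample_observation"),
            inherits(mcmc, "mcmc_config"))
  cnt <- .obs_counts(obs)
  v <- obs$droplet_volume
  sup <- .conc_bounds(obs, cfg)
  lam_hat <- -log1p(-pmin(cnt$k / cnt$n, 1 - 1 / cnt$n)) / v
  floor1 <- 1 / (min(cnt$n) * v)
  cvar0 <- max(if (obs$assay_mode == "CNV_DELETION") lam_hat[2]
               else lam_hat[1] + lam_hat[2], floor1)
  cff0 <- max(lam_hat[3] + lam_hat[4], floor1)
  f_point <- if (lam_hat[3] + lam_hat[4] > 0)
    2 * lam_hat[3] / (lam_hat[3] + lam_hat[4]) else 0.01
  f0 <- min(max(f_point, 0.005), 0.95 * max(cfg$f_max, 1e-6))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(mcmc$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, mcmc$chains)

  chains <- vector("list", mcmc$chains)
  for (i in seq_len(mcmc$chains)) {
    set.seed(chain_seeds[i])
    res <- fc_mcmc_chain(cnt$k, cnt$n, v,
                         as.integer(obs$assay_mode == "CNV_DELETION"),
                         cfg$bias, cfg$f_max, sup$var, sup$ff,
                         cfg$genotype_prior, mcmc$adapt_iters, mcmc$burn_in,
                         mcmc$sampling_iters, f0, cvar0, cff0)
    colnames(res$draws) <- c("f", "conc_var", "conc_ff", "genotype")
    chains[[i]] <- res$draws
  }

  all_draws <- do.call(rbind, chains)
  p_hom <- mean(all_draws[, "genotype"])
  qs <- function(x) stats::setNames(
    stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE),
    c("median", "lower", "upper"))

  diag_params <- c("f", "conc_var", "conc_ff")
  diagnostics <- convergence_diagnostics(
    lapply(chains, function(m) m[, diag_params, drop = FALSE]))
  rh <- diagnostics$rhat[is.finite(diagnostics$rhat)]
  converged <- length(rh) > 0 && all(rh < 1.05)
  if (!converged)
    warning("MCMC convergence not established (R-hat > 1.05 or undefined); ",
            "inspect diagnostics and traces before using this posterior")

  .posterior_summary(p_hom = p_hom, f_post = qs(all_draws[, "f"]),
                     conc_var_post = qs(all_draws[, "conc_var"]),
                     conc_ff_post = qs(all_draws[, "conc_ff"]),
                     engine = "MCMC",
                     total_samples = mcmc$chains * mcmc$sampling_iters,
                     diagnostics = diagnostics, converged = converged,
                     draws = if (keep_draws) chains else NULL)
}

#' Calibrate an assay's reference-allele bias from a heterozygous gDNA control
#'
#' A maternal genomic DNA control is heterozygous by construction, so its
#' two channels should show equal concentrations. The measured ratio
#' `lambda_ref / lambda_var` is the assay's bias factor, to be supplied to
#' [model_config()] so the expected reference fraction is corrected.
#'
#' @param ref_counts,var_counts [channel_counts] of the control's reference
#'   and variant channels.
#' @param droplet_volume Droplet volume in microliters.
#' @return Bias factor (1.0 = unbiased).
#' @examples
#' calibrate_bias(channel_counts(1100, 20000), channel_counts(900, 20000))
#' @export
calibrate_bias <- function(ref_counts, var_counts, droplet_volume = 8.5e-4) {
  if (ref_counts$k == 0L || var_counts$k == 0L)
    stop("cannot calibrate bias: zero positive droplets in a control channel")
  cr <- estimate_concentration(ref_counts, droplet_volume)
  cv <- estimate_concentration(var_counts, droplet_volume)
  cr$lambda / cv$lambda
}

#' Export posterior draws as a flat CSV
#'
#' Writes one row per (chain, iteration, parameter) so traces can be plotted
#' with any external tool.
#'
#' @param post A `posterior_summary` from [run_mcmc()] with retained draws.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
export_draws <- function(post, path) {
  stopifnot(inherits(post, "posterior_summary"))
  if (is.null(post$draws))
    stop("posterior has no retained draws; rerun run_mcmc(keep_draws = TRUE)")
  rows <- do.call(rbind, lapply(seq_along(post$draws), function(i) {
    m <- post$draws[[i]]
    data.frame(chain = i, iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
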