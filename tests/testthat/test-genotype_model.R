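test_that("expected reference fraction encodes the allelic-balance model", {
  expect_identical(expected_ref_fraction("HOM_REF", 0.10), 0.55)
  for (f in c(0, 0.1, 0.3, 0.5)) {
    expect_identical(expected_ref_fraction("HET", f), 0.5)
  }
  expect_identical(expected_ref_fraction("HOM_REF", 0), 0.5)
  expect_error(expected_ref_fraction("HOM_REF", 1.2), "\\[0, 1\\]")
  expect_error(expected_ref_fraction("HOM_AALT", 0.1), "genotype")

  # strictly increasing in f, range [0.5, 0.75] on [0, 0.5] at unit bias
  fs <- seq(0, 0.5, by = 0.01)
  th <- expected_ref_fraction("HOM_REF", fs)
  expect_true(all(diff(th) > 0))
  expect_equal(range(th), c(0.5, 0.75))

  # bias tilts the observed fraction both ways
  expect_gt(expected_ref_fraction("HET", 0.1, bias = 1.2), 0.5)
  expect_lt(expected_ref_fraction("HET", 0.1, bias = 0.8), 0.5)
})

test_that("copy-number ratio counts maternal and fetal reference copies", {
  expect_identical(expected_cnv_ratio("HET_DELETION", 0.2), 0.5)
  expect_identical(expected_cnv_ratio("HOM_REF", 0.2), 0.6)
  expect_identical(expected_cnv_ratio("HOM_REF", 0), 0.5)
  expect_error(expected_cnv_ratio("HOM_REF", -0.1), "\\[0, 1\\]")
})

test_that("log-likelihood matches direct binomial evaluation", {
  obs <- make_obs(3300, 2700, 300, 5700)
  cfg <- model_config(conc_max_var = 1000, conc_max_ff = 1000)
  v <- 8.5e-4; f <- 0.10; cv <- 120; cf <- 120
  # independent evaluation from the model definition
  th <- 0.5 + f / 2
  lam <- c(cv * th, cv * (1 - th), cf * f / 2, cf * (1 - f / 2))
  direct <- sum(dbinom(c(3300, 2700, 300, 5700), 60000,
                       1 - exp(-lam * v), log = TRUE))
  expect_equal(log_likelihood(obs, "HOM_REF", f, cv, cf, cfg), direct)

  # all-zero counts collapse to the closed form -v * sum(n * lambda)
  zero <- make_obs(0, 0, 0, 0)
  expect_equal(log_likelihood(zero, "HOM_REF", f, cv, cf, cfg),
               -v * 60000 * (cv + cf))

  # relabeling symmetry: swapping REF/VAR channels mirrors theta
  a <- make_obs(3300, 2700, 300, 5700)
  b <- make_obs(2700, 3300, 300, 5700)
  expect_equal(log_likelihood(a, "HET", f, cv, cf, cfg),
               log_likelihood(b, "HET", f, cv, cf, cfg))

  # out-of-support parameters reject with -Inf, no exception
  expect_identical(log_likelihood(obs, "HOM_REF", -0.1, cv, cf, cfg), -Inf)
  expect_identical(log_likelihood(obs, "HOM_REF", 0.9, cv, cf, cfg), -Inf)
})

test_that("likelihood peaks near the generating parameters", {
  s <- simulate_sample(simulation_spec(true_f = 0.12, conc_var_total = 60,
                                       conc_ff_total = 60, seed = 31))
  cfg <- model_config()
  at_truth <- log_likelihood(s$observation, "HOM_REF", 0.12, 60, 60, cfg)
  f_wrong <- log_likelihood(s$observation, "HOM_REF", 0.42, 60, 60, cfg)
  expect_gt(at_truth, f_wrong)
})

test_that("quadrature posterior separates genotypes at high information", {
  # variant assay at exact 50:50 with a well-measured 15% fetal fraction:
  # strong evidence against homozygosity
  het_like <- make_obs(3000, 3000, 470, 5800, n = 60000L)
  expect_lte(quadrature_posterior(het_like)$p_hom, 0.05)

  # reference fraction at 0.5 + f/2: strong evidence for homozygosity
  hom_like <- make_obs(3450, 2550, 470, 5800, n = 60000L)
  expect_gte(quadrature_posterior(hom_like)$p_hom, 0.95)
})

test_that("with the fetal-fraction prior collapsed at zero the genotype prior passes through", {
  # no paternal signal: the variant assay then carries no genotype information
  obs <- make_obs(3100, 2900, 0, 5700)
  for (gp in c(0.3, 0.5, 0.8)) {
    ps <- quadrature_posterior(obs, model_config(f_max = 0, genotype_prior = gp))
    expect_equal(ps$p_hom, gp, tolerance = 1e-9)
    expect_equal(unname(ps$f_post["median"]), 0)
  }
})

test_that("posterior homozygosity is nondecreasing in the reference-channel count", {
  p <- vapply(seq(2800, 3600, by = 200), function(k_ref)
    quadrature_posterior(make_obs(k_ref, 2800, 400, 5600))$p_hom, 1)
  expect_true(all(diff(p) >= 0))
})

test_that("high-information calls are insensitive to the vague prior choices", {
  s <- simulate_sample(simulation_spec(true_genotype = "HET", true_f = 0.15,
                                       wells_per_assay = 8, seed = 77))
  base <- quadrature_posterior(s$observation, model_config())$p_hom
  alt_f <- quadrature_posterior(s$observation, model_config(f_max = 0.35))$p_hom
  alt_c <- quadrature_posterior(s$observation,
                                model_config(conc_max_mult = 10))$p_hom
  expect_lt(abs(base - alt_f), 0.01)
  expect_lt(abs(base - alt_c), 0.01)
})

test_that("copy-number deletion mode recovers the fetal genotype", {
  hom <- simulate_sample(simulation_spec(true_genotype = "HOM_REF",
                                         true_f = 0.15, wells_per_assay = 8,
                                         assay_mode = "CNV_DELETION", seed = 91))
  del <- simulate_sample(simulation_spec(true_genotype = "HET_DELETION",
                                         true_f = 0.15, wells_per_assay = 8,
                                         assay_mode = "CNV_DELETION", seed = 92))
  expect_gte(quadrature_posterior(hom$observation)$p_hom, 0.95)
  expect_lte(quadrature_posterior(del$observation)$p_hom, 0.05)
})

test_that("gDNA bias calibration reproduces concentration ratios", {
  expect_equal(calibrate_bias(cc(900), cc(900)), 1.0)
  expect_equal(calibrate_bias(cc(1100), cc(900)), 1.228617, tolerance = 1e-6)
  expect_error(calibrate_bias(cc(0), cc(900)), "zero positive")

  # self-consistency: the biased model predicts the control's own fraction
  b <- calibrate_bias(cc(1100), cc(900))
  ctrl_frac <- fractional_abundance(cc(1100), cc(900))$frac
  expect_equal(expected_ref_fraction("HET", 0, bias = b), ctrl_frac)
  # and correcting by it restores allelic balance at bias 1
  expect_equal(expected_ref_fraction("HET", 0, bias = b / b), 0.5)
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  s <- simulate_sample(simulation_spec(true_genotype = "HOM_REF",
                                       true_f = 0.04, wells_per_assay = 2,
                                       seed = 11))
  o <- s$observation
  va <- o$variant_assay; ff <- o$ff_assay
  lamhat <- function(ch) -log(1 - ch$k / ch$n) / 8.5e-4
  dat <- list(k1 = va$ref$k, n1 = va$ref$n, k2 = va$var$k, n2 = va$var$n,
              k3 = ff$paternal_channel$k, n3 = ff$paternal_channel$n,
              k4 = ff$maternal_channel$k, n4 = ff$maternal_channel$n,
              v = 8.5e-4,
              cvmax = 5 * (lamhat(va$ref) + lamhat(va$var)),
              cfmax = 5 * (lamhat(ff$paternal_channel) +
                             lamhat(ff$maternal_channel)))
  model_str <- "
  model {
    g ~ dbern(0.5)
    f ~ dunif(0, 0.5)
    cvar ~ dunif(0, cvmax)
    cff ~ dunif(0, cfmax)
    theta <- 0.5 + g * f / 2
    k1 ~ dbin(1 - exp(-cvar * theta * v), n1)
    k2 ~ dbin(1 - exp(-cvar * (1 - theta) * v), n2)
    k3 ~ dbin(1 - exp(-cff * f / 2 * v), n3)
    k4 ~ dbin(1 - exp(-cff * (1 - f / 2) * v), n4)
  }"
  inits <- lapply(1:4, function(i)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 1000 + i))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = 4, n.adapt = 1000,
                          quiet = TRUE)
  update(jm, 5000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, "g", 20000, progress.bar = "none")
  p_jags <- mean(unlist(lapply(sm, function(m) m[, "g"])))

  expect_equal(quadrature_posterior(o)$p_hom, p_jags, tolerance = 0.02)
})
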