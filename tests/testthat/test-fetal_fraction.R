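test_that("fetal fraction follows the two-copy-maternal / one-copy-paternal model", {
  obs <- ff_assay_observation(cc(2000), cc(100))
  est <- estimate_fetal_fraction(obs)
  # 2 * (-ln(0.995)) / ((-ln(0.9)) + (-ln(0.995)))
  expect_equal(est$f_hat, 0.09082908, tolerance = 1e-6)
  expect_equal(est$paternal_positive_droplets, 100L)
  expect_true(est$ci_low <= est$f_hat && est$f_hat <= est$ci_high)

  none <- estimate_fetal_fraction(ff_assay_observation(cc(2000), cc(0)))
  expect_equal(none$f_hat, 0)
  expect_error(estimate_fetal_fraction(ff_assay_observation(cc(0), cc(0))),
               "undefined")
})

test_that("fetal fraction estimate is increasing in paternal counts", {
  fs <- vapply(c(0, 10, 100, 500, 1000), function(k)
    estimate_fetal_fraction(ff_assay_observation(cc(2000), cc(k)))$f_hat, 1)
  expect_true(all(diff(fs) > 0))
})

test_that("volume cancels out of the fetal fraction in the rare-target limit", {
  obs <- ff_assay_observation(cc(300), cc(30))  # both k/n < 0.02
  f1 <- estimate_fetal_fraction(obs, droplet_volume = 8.5e-4)$f_hat
  f2 <- estimate_fetal_fraction(obs, droplet_volume = 8.5e-3)$f_hat
  expect_equal(f1, f2, tolerance = 1e-3)
})

test_that("estimator is consistent on simulated male-fetus cfDNA", {
  # ZFX/ZFY design at growing depth: f_hat converges on the truth
  true_f <- 0.08
  for (wells in c(2L, 16L)) {
    s <- simulate_sample(simulation_spec(true_f = true_f, ff_mode = "ZFX_ZFY",
                                         wells_per_assay = wells,
                                         conc_ff_total = 100, seed = 500 + wells))
    est <- estimate_fetal_fraction(s$observation$ff_assay)
    k_pat <- s$observation$ff_assay$paternal_channel$k
    tol <- 3 * true_f / sqrt(k_pat)   # shrinks as 1/sqrt(counts)
    expect_lt(abs(est$f_hat - true_f), tol)
  }
})

test_that("ZFX/ZFY mode refuses a fetus not annotated male", {
  expect_error(ff_assay_observation(cc(2000), cc(100), mode = "ZFX_ZFY"),
               "MALE")
  expect_error(ff_assay_observation(cc(2000), cc(100), mode = "ZFX_ZFY",
                                    fetal_sex = "FEMALE"), "MALE")
  expect_silent(ff_assay_observation(cc(2000), cc(100), mode = "ZFX_ZFY",
                                     fetal_sex = "MALE"))
})

test_that("a 10% fetal-fraction homozygous-reference pregnancy implies 55:45", {
  # engineer counts with f_hat = 0.10 (linear limit), then map the genotype
  obs <- ff_assay_observation(cc(1900, 1e6), cc(100, 1e6))
  f_hat <- estimate_fetal_fraction(obs)$f_hat
  expect_equal(f_hat, 0.10, tolerance = 2e-3)
  expect_equal(expected_ref_fraction("HOM_REF", f_hat), 0.55, tolerance = 1e-3)
})

test_that("QC gates follow the 2% / 10-droplet exclusion rules", {
  mk <- function(f_hat, droplets) {
    structure(list(f_hat = f_hat, paternal_positive_droplets = droplets,
                   ci_low = 0, ci_high = 1), class = "ff_estimate")
  }
  expect_true(qc_sample(mk(0.025, 50))$pass)   # 2.5% supported a call
  low_ff <- qc_sample(mk(0.019, 50))
  expect_false(low_ff$pass)
  expect_equal(low_ff$reasons, "LOW_FETAL_FRACTION")
  low_drop <- qc_sample(mk(0.05, 9))
  expect_false(low_drop$pass)
  expect_equal(low_drop$reasons, "LOW_PATERNAL_DROPLETS")
  # boundary values pass (thresholds are "at least")
  expect_true(qc_sample(mk(0.02, 10))$pass)
  ntc_bad <- qc_sample(mk(0.05, 50), ntc = list(pass = FALSE))
  expect_equal(ntc_bad$reasons, "NTC_FAIL")
  both <- qc_sample(mk(0.01, 5))
  expect_setequal(both$reasons, c("LOW_FETAL_FRACTION", "LOW_PATERNAL_DROPLETS"))
  expect_false(both$pass)
})

test_that("candidate paternal SNVs are kept on the closed 1%-15% range", {
  tab <- data.frame(snv_id = letters[1:5],
                    minor_allele_fraction = c(0.005, 0.01, 0.08, 0.15, 0.2))
  kept <- filter_candidate_paternal_snvs(tab)
  expect_equal(kept$snv_id, c("b", "c", "d"))

  empty <- filter_candidate_paternal_snvs(tab[0, ])
  expect_equal(nrow(empty), 0L)

  homs <- data.frame(snv_id = c("x", "y"), minor_allele_fraction = c(0.5, 0.5))
  expect_equal(nrow(filter_candidate_paternal_snvs(homs)), 0L)

  bad <- data.frame(snv_id = "z", minor_allele_fraction = 1.2)
  expect_error(filter_candidate_paternal_snvs(bad), "\\[0, 1\\]")
})
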