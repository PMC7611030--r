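# minimal posterior / QC stubs for decision-layer tests
post_stub <- function(p_hom, f = 0.1) {
  structure(list(p_hom = p_hom,
                 f_post = c(median = f, lower = f / 2, upper = 2 * f),
                 engine = "QUADRATURE", total_samples = NA_integer_,
                 converged = NA),
            class = "posterior_summary")
}
qc_stub <- function(pass = TRUE, reasons = character(0)) {
  structure(list(pass = pass, reasons = reasons), class = "sample_qc")
}
call_stub <- function(call, p_hom = NA_real_) {
  structure(list(sample_id = "s", call = call, p_hom = p_hom, f_hat = 0.1,
                 reasons = character(0)), class = "genotype_call")
}

test_that("genotype calls follow the inclusive 0.95/0.05 thresholds", {
  thr <- call_thresholds()
  expect_identical(call_genotype(post_stub(0.99), qc_stub(), thr)$call, "HOM_REF")
  expect_identical(call_genotype(post_stub(0.95), qc_stub(), thr)$call, "HOM_REF")
  expect_identical(call_genotype(post_stub(0.05), qc_stub(), thr)$call, "HET")
  expect_identical(call_genotype(post_stub(0.01), qc_stub(), thr)$call, "HET")
  mid <- call_genotype(post_stub(0.50), qc_stub(), thr)
  expect_identical(mid$call, "NO_CALL_INTERMEDIATE")
  expect_identical(mid$reasons, "INTERMEDIATE_PROBABILITY")
  expect_error(call_thresholds(0.05, 0.95), "p_het_call < p_hom_call")
})

test_that("raising p_hom never moves a call toward heterozygous", {
  rank <- c(HET = 1, NO_CALL_INTERMEDIATE = 2, HOM_REF = 3)
  calls <- vapply(seq(0, 1, by = 0.01), function(p)
    call_genotype(post_stub(p), qc_stub())$call, "")
  expect_true(all(diff(rank[calls]) >= 0))
})

test_that("QC failure dominates any posterior", {
  qc_bad <- qc_stub(FALSE, "LOW_FETAL_FRACTION")
  for (p in c(0.001, 0.5, 0.999)) {
    cl <- call_genotype(post_stub(p), qc_bad)
    expect_identical(cl$call, "QC_FAIL")
    expect_true(is.na(cl$p_hom))
    expect_identical(cl$reasons, "LOW_FETAL_FRACTION")
  }
  # even without a posterior at all
  expect_identical(call_genotype(NULL, qc_bad)$call, "QC_FAIL")
})

test_that("pregnancies resolve on the first conclusive sample in gestational order", {
  pr <- evaluate_pregnancy(list(call_stub("NO_CALL_INTERMEDIATE", 0.5),
                                call_stub("HOM_REF", 0.99)),
                           pregnancy_id = "p1")
  expect_identical(pr$final_call, "HOM_REF")
  expect_identical(pr$n_samples_used, 2L)

  expect_identical(evaluate_pregnancy(list(call_stub("QC_FAIL")))$final_call,
                   "UNRESOLVED")
  one <- evaluate_pregnancy(list(call_stub("HET", 0.01)))
  expect_identical(one$final_call, "HET")
  expect_identical(one$n_samples_used, 1L)

  # samples are walked by gestational age, not input order
  ordered <- evaluate_pregnancy(list(call_stub("HOM_REF", 0.99),
                                     call_stub("QC_FAIL")),
                                gestation_weeks = c(30, 12),
                                pregnancy_id = "p2")
  expect_identical(ordered$n_samples_used, 2L)
  expect_warning(
    evaluate_pregnancy(list(call_stub("HET", 0.01), call_stub("QC_FAIL")),
                       gestation_weeks = c(12, NA), pregnancy_id = "p3"),
    "missing gestational age")
})

test_that("conflicting conclusive calls within a pregnancy are an error", {
  expect_error(
    evaluate_pregnancy(list(call_stub("HOM_REF", 0.99),
                            call_stub("HET", 0.01)), pregnancy_id = "p4"),
    "conflicting conclusive calls")
})

test_that("cohort summary reproduces the clinical sensitivity/specificity arithmetic", {
  # 33 of 38 pregnancies called, all correct
  results <- lapply(1:38, function(i) {
    final <- if (i <= 33) if (i %% 2 == 0) "HOM_REF" else "HET" else "UNRESOLVED"
    structure(list(pregnancy_id = paste0("p", i),
                   calls = list(), final_call = final, n_samples_used = 1L),
              class = "pregnancy_result")
  })
  truth <- setNames(ifelse(1:38 %% 2 == 0, "HOM_REF", "HET"),
                    paste0("p", 1:38))
  cs <- cohort_summary(results, truth)
  expect_identical(cs$n_called, 33L)
  expect_equal(round(100 * cs$sensitivity, 1), 86.8)
  expect_equal(cs$specificity, 1.0)
  expect_identical(sum(cs$confusion), 38L)

  # a wrong call costs both sensitivity and specificity
  results[[1]]$final_call <- "HOM_REF"  # truth is HET
  cs2 <- cohort_summary(results, truth)
  expect_equal(cs2$sensitivity, 32 / 38)
  expect_equal(cs2$specificity, 32 / 33)

  unresolved <- lapply(results[1:3], function(r) {
    r$final_call <- "UNRESOLVED"; r
  })
  cs3 <- cohort_summary(unresolved, truth)
  expect_equal(cs3$sensitivity, 0)
  expect_true(is.na(cs3$specificity))

  expect_error(cohort_summary(results[1:2], truth[3:4]), "missing truth")
})

test_that("a high-information simulated cohort is called perfectly end to end", {
  cohort <- simulate_cohort(10, f_range = c(0.08, 0.25),
                            spec = simulation_spec(wells_per_assay = 8),
                            seed = 404)
  results <- lapply(cohort, function(s) {
    ff <- estimate_fetal_fraction(s$observation$ff_assay)
    qc <- qc_sample(ff)
    post <- quadrature_posterior(s$observation)
    cl <- call_genotype(post, qc, sample_id = s$observation$sample_id)
    evaluate_pregnancy(list(cl), pregnancy_id = s$observation$pregnancy_id)
  })
  truth <- setNames(vapply(cohort, function(s) s$truth$genotype, ""),
                    vapply(cohort, function(s) s$observation$pregnancy_id, ""))
  cs <- cohort_summary(results, truth)
  expect_identical(cs$n_called, 10L)
  expect_equal(cs$sensitivity, 1.0)
  expect_equal(cs$specificity, 1.0)
})
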