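#' Probability thresholds for genotype calling
#'
#' A sample is called homozygous reference when the posterior probability of
#' fetal homozygosity is at least `p_hom_call` (default 0.95) and
#' heterozygous when it is at most `p_het_call` (default 0.05); both
#' comparisons are inclusive. Anything in between is reported as an
#' intermediate no-call.
#'
#' @param p_hom_call,p_het_call Call thresholds with
#'   `0 < p_het_call < p_hom_call < 1`.
#' @return An object of class `call_thresholds`.
#' @export
call_thresholds <- function(p_hom_call = 0.95, p_het_call = 0.05) {
  if (!(p_het_call > 0 && p_het_call < p_hom_call && p_hom_call < 1))
    stop("need 0 < p_het_call < p_hom_call < 1")
  structure(list(p_hom_call = p_hom_call, p_het_call = p_het_call),
            class = "call_thresholds")
}

#' Call a fetal genotype for one plasma sample
#'
#' QC failure dominates: a sample failing the fetal-fraction or
#' paternal-droplet gates is reported `QC_FAIL` and its posterior is not
#' used for calling, whatever its value.
#'
#' @param post A `posterior_summary` (either engine).
#' @param qc A `sample_qc` from [qc_sample()].
#' @param thresholds A [call_thresholds].
#' @param sample_id Optional identifier carried into the call.
#' @return An object of class `genotype_call` with `call` (one of
#'   `HOM_REF`, `HET`, `NO_CALL_INTERMEDIATE`, `QC_FAIL`), `p_hom`, `f_hat`
#'   (posterior median fetal fraction, `NA` on QC failure) and `reasons`.
#' @export
call_genotype <- function(post, qc, thresholds = call_thresholds(),
                          sample_id = NA_character_) {
  stopifnot(inherits(qc, "sample_qc"), inherits(thresholds, "call_thresholds"))
  if (!qc$pass) {
    return(structure(list(sample_id = sample_id, call = "QC_FAIL",
                          p_hom = NA_real_, f_hat = NA_real_,
                          reasons = qc$reasons),
                     class = "genotype_call"))
  }
  stopifnot(inherits(post, "posterior_summary"))
  call <- if (post$p_hom >= thresholds$p_hom_call) "HOM_REF"
          else if (post$p_hom <= thresholds$p_het_call) "HET"
          else "NO_CALL_INTERMEDIATE"
  reasons <- if (call == "NO_CALL_INTERMEDIATE") "INTERMEDIATE_PROBABILITY"
             else character(0)
  if (isFALSE(post$converged)) reasons <- c(reasons, "MCMC_NOT_CONVERGED")
  structure(list(sample_id = sample_id, call = call, p_hom = post$p_hom,
                 f_hat = post$f_post[["median"]], reasons = reasons),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s: %s (p_hom = %s)%s\n",
              ifelse(is.na(x$sample_id), "sample", x$sample_id), x$call,
              ifelse(is.na(x$p_hom), "NA", sprintf("%.4f", x$p_hom)),
              if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Resolve a pregnancy from its samples' calls
#'
#' Samples are walked in gestational order (missing gestational ages sort
#' last, with a warning): the first conclusive call (`HOM_REF` or `HET`)
#' fixes the pregnancy's final call, while `QC_FAIL` and
#' `NO_CALL_INTERMEDIATE` hand over to the next (follow-up) sample. With no
#' conclusive sample the pregnancy is `UNRESOLVED`. Conflicting conclusive
#' calls among a pregnancy's samples are an error: concordance between
#' samples of one pregnancy is expected, so a conflict means something is
#' wrong upstream.
#'
#' @param calls List of `genotype_call` objects for one pregnancy.
#' @param gestation_weeks Optional numeric vector (same length) used to
#'   order the samples.
#' @param pregnancy_id Identifier for the result.
#' @return An object of class `pregnancy_result` with `final_call`
#'   (`HOM_REF`, `HET` or `UNRESOLVED`), `n_samples_used` (samples examined
#'   up to and including the deciding one) and the per-sample calls in the
#'   order walked.
#' @export
evaluate_pregnancy <- function(calls, gestation_weeks = NULL,
                               pregnancy_id = NA_character_) {
  stopifnot(length(calls) >= 1L,
            all(vapply(calls, inherits, TRUE, "genotype_call")))
  ord <- seq_along(calls)
  if (!is.null(gestation_weeks)) {
    stopifnot(length(gestation_weeks) == length(calls))
    if (anyNA(gestation_weeks))
      warning("samples with missing gestational age sort last within pregnancy ",
              pregnancy_id)
    ord <- order(gestation_weeks, na.last = TRUE)
  }
  calls <- calls[ord]
  verdicts <- vapply(calls, `[[`, "", "call")
  conclusive <- verdicts[verdicts %in% c("HOM_REF", "HET")]
  if (length(unique(conclusive)) > 1L)
    stop("conflicting conclusive calls within pregnancy ", pregnancy_id, ": ",
         paste(conclusive, collapse = ", "))
  first <- match(TRUE, verdicts %in% c("HOM_REF", "HET"))
  final <- if (is.na(first)) "UNRESOLVED" else verdicts[first]
  structure(list(pregnancy_id = pregnancy_id, calls = calls,
                 final_call = final,
                 n_samples_used = if (is.na(first)) length(calls) else first),
            class = "pregnancy_result")
}

#' @export
print.pregnancy_result <- function(x, ...) {
  cat(sprintf("<pregnancy_result> %s: %s (from %d of %d sample%s)\n",
              ifelse(is.na(x$pregnancy_id), "pregnancy", x$pregnancy_id),
              x$final_call, x$n_samples_used, length(x$calls),
              if (length(x$calls) > 1L) "s" else ""))
  invisible(x)
}

#' Cohort-level diagnostic performance
#'
#' Summarizes pregnancy results against confirmed genotypes.
#' "Sensitivity" follows the clinical-yield usage: conclusive *and* correct
#' calls over all pregnancies (so unresolved pregnancies count against it),
#' while "specificity" is the fraction of conclusive calls that are correct
#' (1 minus the false-call rate among calls; `NA` when nothing was called).
#' The raw confusion table is returned so alternative definitions can be
#' computed.
#'
#' @param results List of `pregnancy_result` objects.
#' @param truth Named character vector (or data frame with `pregnancy_id`,
#'   `genotype`) of confirmed genotypes, `HOM_REF`/`HET`, one per pregnancy.
#' @return An object of class `cohort_summary`: `n_total`, `n_called`,
#'   `n_correct`, `sensitivity`, `specificity`, `concordance` (fraction of
#'   calls matching truth) and `confusion` (truth x call table).
#' @export
cohort_summary <- function(results, truth) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "pregnancy_result")))
  if (is.data.frame(truth)) {
    stopifnot(all(c("pregnancy_id", "genotype") %in% names(truth)))
    truth <- stats::setNames(as.character(truth$genotype),
                             as.character(truth$pregnancy_id))
  }
  ids <- vapply(results, `[[`, "", "pregnancy_id")
  if (!all(ids %in% names(truth)))
    stop("missing truth genotype for pregnancies: ",
         paste(setdiff(ids, names(truth)), collapse = ", "))
  if (!all(truth[ids] %in% c("HOM_REF", "HET")))
    stop("truth genotypes must be HOM_REF or HET")
  finals <- vapply(results, `[[`, "", "final_call")
  tr <- truth[ids]
  called <- finals %in% c("HOM_REF", "HET")
  correct <- called & finals == tr
  n_total <- length(results)
  n_called <- sum(called)
  confusion <- table(truth = factor(tr, c("HOM_REF", "HET")),
                     call = factor(finals, c("HOM_REF", "HET", "UNRESOLVED")))
  structure(list(
    n_total = n_total, n_called = n_called, n_correct = sum(correct),
    sensitivity = sum(correct) / n_total,
    specificity = if (n_called > 0) sum(correct) / n_called else NA_real_,
    concordance = if (n_called > 0) sum(correct) / n_called else NA_real_,
    confusion = confusion), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d/%d pregnancies called (%d correct)\n",
              x$n_called, x$n_total, x$n_correct))
  cat(sprintf("  clinical sensitivity: %.1f%%  specificity: %s\n",
              100 * x$sensitivity,
              ifelse(is.na(x$specificity), "NA",
                     sprintf("%.1f%%", 100 * x$specificity))))
  print(x$confusion)
  invisible(x)
}
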