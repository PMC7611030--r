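#' Fetal-fraction assay observation
#'
#' Pairs the two channels of a fetal-fraction ddPCR assay: the allele shared
#' with the mother (or ZFX) and the paternal-only allele (or ZFY, male
#' fetuses). In `OPPOSITE_HOMOZYGOTE_SNP` mode the parents are opposite
#' homozygotes at a common SNP so the paternal allele is uniquely fetal; in
#' `ZFX_ZFY` mode the Y-linked target plays that role and the mode is only
#' valid for a fetus annotated male.
#'
#' @param maternal_channel [channel_counts] for the maternally shared target.
#' @param paternal_channel [channel_counts] for the paternal-only target.
#' @param mode `"OPPOSITE_HOMOZYGOTE_SNP"` or `"ZFX_ZFY"`.
#' @param fetal_sex `"MALE"`, `"FEMALE"` or `NA` (unknown). `ZFX_ZFY` mode
#'   requires `"MALE"`.
#' @return An object of class `ff_assay_observation`.
#' @export
ff_assay_observation <- function(maternal_channel, paternal_channel,
                                 mode = c("OPPOSITE_HOMOZYGOTE_SNP", "ZFX_ZFY"),
                                 fetal_sex = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(maternal_channel, "channel_counts"),
            inherits(paternal_channel, "channel_counts"))
  if (mode == "ZFX_ZFY" && (is.na(fetal_sex) || fetal_sex != "MALE"))
    stop("ZFX_ZFY fetal-fraction mode requires a fetus annotated MALE; ",
         "use OPPOSITE_HOMOZYGOTE_SNP mode for female or unknown-sex pregnancies")
  structure(list(maternal_channel = maternal_channel,
                 paternal_channel = paternal_channel,
                 mode = mode, fetal_sex = fetal_sex),
            class = "ff_assay_observation")
}

#' Estimate the fetal fraction from a paternal-allele assay
#'
#' The mother contributes two copies of the maternal-channel target per
#' genome while the fetus contributes one maternal-channel and one
#' paternal-only copy, so the paternal channel carries a share `f/2` of the
#' assay's total concentration and
#' `f = 2 * lambda_pat / (lambda_pat + lambda_mat)`. The same formula covers
#' both the opposite-homozygote SNP and the ZFX/ZFY (male fetus) designs.
#' The CI propagates the per-channel concentration CIs at paired extremes and
#' doubles, clamped to `[0, 1]`.
#'
#' @param obs An [ff_assay_observation].
#' @param droplet_volume Droplet volume in microliters.
#' @return An object of class `ff_estimate` with `f_hat`,
#'   `paternal_positive_droplets`, `ci_low`, `ci_high`.
#' @examples
#' obs <- ff_assay_observation(channel_counts(2000, 20000),
#'                             channel_counts(100, 20000))
#' estimate_fetal_fraction(obs)
#' @export
estimate_fetal_fraction <- function(obs, droplet_volume = 8.5e-4) {
  stopifnot(inherits(obs, "ff_assay_observation"))
  if (obs$maternal_channel$k == 0L && obs$paternal_channel$k == 0L)
    stop("no positive droplets in either channel: fetal fraction undefined")
  cm <- estimate_concentration(obs$maternal_channel, droplet_volume)
  cp <- estimate_concentration(obs$paternal_channel, droplet_volume)
  f_hat <- min(1, 2 * cp$lambda / (cp$lambda + cm$lambda))
  lo <- if (cp$ci_low + cm$ci_high == 0) 0
        else 2 * cp$ci_low / (cp$ci_low + cm$ci_high)
  hi <- if (is.infinite(cp$ci_high)) 1
        else 2 * cp$ci_high / (cp$ci_high + cm$ci_low)
  structure(list(f_hat = f_hat,
                 paternal_positive_droplets = obs$paternal_channel$k,
                 ci_low = max(0, min(lo, 1)), ci_high = max(0, min(hi, 1))),
            class = "ff_estimate")
}

#' @export
print.ff_estimate <- function(x, ...) {
  cat(sprintf(
    "<ff_estimate> fetal fraction %.3f (95%% CI %.3f-%.3f), %d paternal-positive droplets\n",
    x$f_hat, x$ci_low, x$ci_high, x$paternal_positive_droplets))
  invisible(x)
}

#' Sample-level quality-control gates
#'
#' A plasma sample is only eligible for genotype calling when the point
#' estimate of fetal fraction is at least `min_ff` (default 2%), the
#' fetal-fraction assay saw at least `min_paternal_droplets` positive
#' droplets for the paternal allele (default 10), and the run's no-template
#' controls were clean. QC uses the point estimate, mirroring a pre-model
#' exclusion step: the posterior fetal fraction plays no role here.
#'
#' @param ff An [ff_estimate].
#' @param ntc Result of [check_ntc()], or `NULL` to skip the NTC gate.
#' @param min_ff Minimum fetal fraction (default 0.02).
#' @param min_paternal_droplets Minimum paternal-allele positive droplets
#'   (default 10).
#' @return An object of class `sample_qc` with `pass` (logical) and
#'   `reasons` (character vector among `LOW_FETAL_FRACTION`,
#'   `LOW_PATERNAL_DROPLETS`, `NTC_FAIL`); `pass` is `TRUE` iff `reasons`
#'   is empty.
#' @examples
#' ff <- list(f_hat = 0.019, paternal_positive_droplets = 50)
#' class(ff) <- "ff_estimate"
#' qc_sample(ff)
#' @export
qc_sample <- function(ff, ntc = NULL, min_ff = 0.02,
                      min_paternal_droplets = 10L) {
  stopifnot(inherits(ff, "ff_estimate"))
  reasons <- character(0)
  if (ff$f_hat < min_ff) reasons <- c(reasons, "LOW_FETAL_FRACTION")
  if (ff$paternal_positive_droplets < min_paternal_droplets)
    reasons <- c(reasons, "LOW_PATERNAL_DROPLETS")
  if (!is.null(ntc) && !ntc$pass) reasons <- c(reasons, "NTC_FAIL")
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 min_ff = min_ff,
                 min_paternal_droplets = min_paternal_droplets),
            class = "sample_qc")
}

#' @export
print.sample_qc <- function(x, ...) {
  if (x$pass) cat("<sample_qc> PASS\n")
  else cat("<sample_qc> FAIL:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Filter candidate paternally inherited SNVs by allele fraction
#'
#' From cfDNA sequencing of a pregnancy with no paternal gDNA available,
#' candidate paternal alleles are those whose minor allele fraction sits in
#' the range expected for a bona fide paternally inherited allele, 1%-15%
#' (inclusive bounds): roughly half the fetal fraction, well below the
#' signal of any maternal heterozygous site.
#'
#' @param snvs Data frame with columns `snv_id` and `minor_allele_fraction`.
#' @param min_fraction,max_fraction Inclusive bounds (defaults 0.01, 0.15).
#' @return The subset of rows whose fraction lies within the bounds.
#' @examples
#' filter_candidate_paternal_snvs(data.frame(
#'   snv_id = c("a", "b", "c"), minor_allele_fraction = c(0.005, 0.08, 0.5)))
#' @export
filter_candidate_paternal_snvs <- function(snvs, min_fraction = 0.01,
                                           max_fraction = 0.15) {
  stopifnot(is.data.frame(snvs))
  if (nrow(snvs) == 0L) return(snvs)
  if (!all(c("snv_id", "minor_allele_fraction") %in% names(snvs)))
    stop("snvs must have columns 'snv_id' and 'minor_allele_fraction'")
  maf <- snvs$minor_allele_fraction
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 1))
    stop("minor_allele_fraction must lie in [0, 1]")
  snvs[maf >= min_fraction & maf <= max_fraction, , drop = FALSE]
}
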