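#' Specification for one simulated plasma sample
#'
#' Ground truth and assay geometry for the droplet-count simulator. The
#' defaults emulate a realistic clinical run: 15 000 accepted droplets per
#' well, 0.85 nL droplets, four replicate wells per assay and total assay
#' concentrations of 50 copies/uL (roughly 600 positive droplets per
#' channel per well at allelic balance).
#'
#' @param true_genotype `"HOM_REF"`, `"HET"` or (CNV mode) `"HET_DELETION"`.
#' @param true_f True fetal fraction in `[0, 1]`.
#' @param conc_var_total Variant-assay total concentration, copies/uL (in
#'   CNV mode, the reference-locus concentration).
#' @param conc_ff_total Fetal-fraction-assay total concentration, copies/uL.
#' @param droplet_volume Droplet volume, microliters.
#' @param droplets_per_well Accepted droplets per well.
#' @param wells_per_assay Replicate wells per assay, 1-16.
#' @param bias Reference-allele bias factor of the variant assay.
#' @param assay_mode `"ALLELIC"` or `"CNV_DELETION"`.
#' @param ff_mode Fetal-fraction assay design (see [ff_assay_observation()]).
#' @param seed Optional integer seed for a deterministic sample.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(true_genotype = "HOM_REF", true_f = 0.10,
                            conc_var_total = 50, conc_ff_total = 50,
                            droplet_volume = 8.5e-4,
                            droplets_per_well = 15000L,
                            wells_per_assay = 4L, bias = 1,
                            assay_mode = c("ALLELIC", "CNV_DELETION"),
                            ff_mode = "OPPOSITE_HOMOZYGOTE_SNP",
                            seed = NULL) {
  assay_mode <- match.arg(assay_mode)
  true_genotype <- .norm_genotype(true_genotype)
  stopifnot(true_f >= 0, true_f <= 1, conc_var_total > 0, conc_ff_total > 0,
            droplet_volume > 0, droplets_per_well >= 1,
            wells_per_assay >= 1, wells_per_assay <= 16, bias > 0)
  structure(list(true_genotype = true_genotype, true_f = true_f,
                 conc_var_total = conc_var_total,
                 conc_ff_total = conc_ff_total,
                 droplet_volume = droplet_volume,
                 droplets_per_well = as.integer(droplets_per_well),
                 wells_per_assay = as.integer(wells_per_assay),
                 bias = bias, assay_mode = assay_mode, ff_mode = ff_mode,
                 seed = seed),
            class = "simulation_spec")
}

#' Simulate one well's droplet counts
#'
#' Droplet occupancy is simulated directly at the partition level: each of
#' `n_droplets` droplets is positive with probability
#' `1 - exp(-lam * droplet_volume)`, independently per channel. This is
#' distributionally identical to seeding Poisson molecule counts per
#' droplet, without per-droplet bookkeeping.
#'
#' @param lam Named or unnamed numeric vector of channel concentrations
#'   (copies/uL).
#' @param n_droplets Accepted droplets in the well.
#' @param droplet_volume Droplet volume, microliters.
#' @return Integer vector of positive-droplet counts, one per channel.
#' @export
simulate_well <- function(lam, n_droplets, droplet_volume = 8.5e-4) {
  stopifnot(all(lam >= 0), n_droplets >= 1, droplet_volume > 0)
  p <- -expm1(-lam * droplet_volume)
  stats::rbinom(length(lam), n_droplets, p)
}

#' Simulate a complete plasma sample
#'
#' Channel concentrations are derived from the truth exactly as the
#' likelihood parameterizes them (expected reference fraction for the
#' variant assay, `f/2` paternal share for the fetal-fraction assay), wells
#' are generated independently and merged, and the truth is retained
#' alongside the observation for scoring.
#'
#' @param spec A [simulation_spec].
#' @param sample_id,pregnancy_id Identifiers for the resulting observation.
#' @return An object of class `simulated_sample`: a list with `observation`
#'   (a [sample_observation]) and `truth` (genotype, fetal fraction,
#'   concentrations, per-channel rates).
#' @export
simulate_sample <- function(spec, sample_id = "sim1",
                            pregnancy_id = sample_id) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  if (spec$assay_mode == "CNV_DELETION") {
    r <- expected_cnv_ratio(spec$true_genotype, spec$true_f)
    lam12 <- c(spec$conc_var_total * r, spec$conc_var_total)
  } else {
    th <- expected_ref_fraction(spec$true_genotype, spec$true_f, spec$bias)
    lam12 <- c(spec$conc_var_total * th, spec$conc_var_total * (1 - th))
  }
  lam <- c(lam12, spec$conc_ff_total * spec$true_f / 2,
           spec$conc_ff_total * (1 - spec$true_f / 2))

  wells <- t(vapply(seq_len(spec$wells_per_assay), function(i)
    simulate_well(lam, spec$droplets_per_well, spec$droplet_volume),
    integer(4)))
  cc <- function(j) channel_counts(sum(wells[, j]),
                                   spec$wells_per_assay * spec$droplets_per_well,
                                   spec$wells_per_assay)
  variant <- if (spec$assay_mode == "CNV_DELETION")
    list(target = cc(1), ref_locus = cc(2)) else list(ref = cc(1), var = cc(2))
  ff <- ff_assay_observation(maternal_channel = cc(4), paternal_channel = cc(3),
                             mode = spec$ff_mode,
                             fetal_sex = if (spec$ff_mode == "ZFX_ZFY") "MALE"
                                         else NA_character_)
  obs <- sample_observation(sample_id, variant, ff,
                            pregnancy_id = pregnancy_id,
                            droplet_volume = spec$droplet_volume,
                            assay_mode = spec$assay_mode)

  chan_roles <- c(if (spec$assay_mode == "CNV_DELETION")
                    c("CNV_TARGET", "CNV_REFERENCE_LOCUS")
                  else c("REF_ALLELE", "VAR_ALLELE"),
                  "PATERNAL_ALLELE", "MATERNAL_ALLELE")
  assay_of <- c("var", "var", "ff", "ff")
  well_table <- do.call(rbind, lapply(1:4, function(j)
    data.frame(well_id = sprintf("%s_%s_w%02d", sample_id, assay_of[j],
                                 seq_len(spec$wells_per_assay)),
               sample_id = sample_id, pregnancy_id = pregnancy_id,
               assay_id = paste0(sample_id, "_", assay_of[j]),
               assay_role = ifelse(assay_of[j] == "var", "VARIANT",
                                   "FETAL_FRACTION"),
               channel_role = chan_roles[j], positive = wells[, j],
               total = spec$droplets_per_well,
               ff_mode = spec$ff_mode,
               fetal_sex = if (spec$ff_mode == "ZFX_ZFY") "MALE"
                           else NA_character_,
               stringsAsFactors = FALSE)))
  structure(list(observation = obs, well_table = well_table,
                 truth = list(genotype = spec$true_genotype, f = spec$true_f,
                              conc_var_total = spec$conc_var_total,
                              conc_ff_total = spec$conc_ff_total,
                              lambda = lam)),
            class = "simulated_sample")
}

#' Simulate a cohort of pregnancies
#'
#' Fetal fractions are drawn uniformly from `f_range`, defaulting to
#' 2.5%-26.1%, the envelope observed across callable clinical samples;
#' genotypes are Bernoulli draws with probability `genotype_prior` of
#' homozygous reference (0.5: Mendelian segregation from a heterozygous
#' mother).
#'
#' @param n_pregnancies Number of pregnancies (one sample each).
#' @param f_range Range of true fetal fractions (uniform draw).
#' @param genotype_prior Probability a fetus is homozygous reference.
#' @param spec A [simulation_spec] providing assay geometry defaults; its
#'   `true_genotype`, `true_f` and `seed` fields are overridden per sample.
#' @param seed Integer seed for the whole cohort.
#' @return List of `simulated_sample` objects with sample ids
#'   `"sim001"`, ... and matching pregnancy ids.
#' @export
simulate_cohort <- function(n_pregnancies, f_range = c(0.025, 0.261),
                            genotype_prior = 0.5,
                            spec = simulation_spec(), seed = 1L) {
  stopifnot(n_pregnancies >= 1, length(f_range) == 2L,
            f_range[1] >= 0, f_range[2] <= 1, f_range[1] <= f_range[2],
            genotype_prior >= 0, genotype_prior <= 1)
  set.seed(seed)
  fs <- stats::runif(n_pregnancies, f_range[1], f_range[2])
  homs <- stats::rbinom(n_pregnancies, 1, genotype_prior) == 1
  lapply(seq_len(n_pregnancies), function(i) {
    s <- spec
    s$true_f <- fs[i]
    s$true_genotype <- if (homs[i]) "HOM_REF" else "HET"
    s$seed <- NULL  # keep the cohort on one RNG stream
    id <- sprintf("sim%03d", i)
    simulate_sample(s, sample_id = id, pregnancy_id = id)
  })
}
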