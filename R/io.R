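.assay_roles <- c("VARIANT", "FETAL_FRACTION", "NTC", "GDNA_CONTROL")
.role_channels <- list(
  VARIANT = c("REF_ALLELE", "VAR_ALLELE", "CNV_TARGET", "CNV_REFERENCE_LOCUS"),
  FETAL_FRACTION = c("MATERNAL_ALLELE", "PATERNAL_ALLELE"),
  NTC = .channel_roles,
  GDNA_CONTROL = c("REF_ALLELE", "VAR_ALLELE"))

#' Read and validate a long-format well table
#'
#' One row per well x channel. Required columns: `well_id`, `sample_id`,
#' `assay_id`, `assay_role` (`VARIANT`, `FETAL_FRACTION`, `NTC`,
#' `GDNA_CONTROL`), `channel_role`, `positive`, `total`. Optional:
#' `pregnancy_id` (defaults to `sample_id`), `gestation_weeks`, `ff_mode`,
#' `fetal_sex`. Counts must be nonnegative integers with
#' `positive <= total`; violations are reported with their row numbers.
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_well_table <- function(path) {
  if (!file.exists(path)) stop("well table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_well_table(tab)
}

#' Validate an in-memory well table
#'
#' @param tab Data frame laid out as in [read_well_table()].
#' @return The validated (and completed) data frame.
#' @export
validate_well_table <- function(tab) {
  required <- c("well_id", "sample_id", "assay_id", "assay_role",
                "channel_role", "positive", "total")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("well table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0L) stop("well table has no rows")
  if (!"pregnancy_id" %in% names(tab)) tab$pregnancy_id <- tab$sample_id
  if (!"gestation_weeks" %in% names(tab)) tab$gestation_weeks <- NA_real_
  for (col in c("well_id", "sample_id", "pregnancy_id", "assay_id",
                "assay_role", "channel_role", "ff_mode", "fetal_sex")) {
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  }
  tab$gestation_weeks <- as.numeric(tab$gestation_weeks)

  bad_rows <- function(cond, what) {
    if (any(cond))
      stop(sprintf("well table row%s %s: %s",
                   if (sum(cond) > 1L) "s" else "",
                   paste(which(cond), collapse = ", "), what))
  }
  num_ok <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  bad_rows(!num_ok(tab$positive) | !num_ok(tab$total), "non-numeric counts")
  tab$positive <- as.numeric(tab$positive); tab$total <- as.numeric(tab$total)
  bad_rows(tab$positive %% 1 != 0 | tab$total %% 1 != 0,
           "fractional droplet counts (counts must be raw integers; merging happens inside the tool)")
  bad_rows(tab$positive < 0, "negative positive-droplet counts")
  bad_rows(tab$total <= 0, "total accepted droplets must be > 0")
  bad_rows(tab$positive > tab$total, "positive exceeds total droplets")
  tab$positive <- as.integer(tab$positive); tab$total <- as.integer(tab$total)
  bad_rows(!tab$assay_role %in% .assay_roles,
           paste("unknown assay_role (expected",
                 paste(.assay_roles, collapse = "/"), ")"))
  bad_rows(!tab$channel_role %in% .channel_roles, "unknown channel_role")
  ok_chan <- mapply(function(a, ch) ch %in% .role_channels[[a]],
                    tab$assay_role, tab$channel_role)
  bad_rows(!ok_chan, "channel_role not valid for assay_role")
  tab
}

#' Write a well table CSV
#'
#' @param tab A well table data frame (validated on the way out).
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_well_table <- function(tab, path) {
  tab <- validate_well_table(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Well table for a simulated cohort
#'
#' Expands simulated samples back into per-well rows (the layout
#' [read_well_table()] accepts) so simulated data can exercise the full
#' pipeline path, including parsing.
#'
#' @param cohort List of `simulated_sample` objects (see
#'   [simulate_cohort()]).
#' @return A well table data frame.
#' @export
cohort_well_table <- function(cohort) {
  stopifnot(length(cohort) >= 1L,
            all(vapply(cohort, inherits, TRUE, "simulated_sample")))
  do.call(rbind, lapply(cohort, function(s) s$well_table))
}

#' Run configuration
#'
#' All tunable constants of the pipeline in one place. Defaults are the
#' reference operating point: 0.85 nL droplets, 2% minimum fetal fraction,
#' 10 minimum paternal-allele droplets, clean NTCs, 0.95/0.05 call
#' thresholds, Uniform(0, 0.5) fetal-fraction prior, 0.5 genotype prior and
#' the 4-chain 1000/10000/50000 MCMC schedule.
#'
#' @param droplet_volume Droplet volume, microliters.
#' @param min_ff,min_paternal_droplets,max_ntc_positive QC gates.
#' @param p_hom_call,p_het_call Call thresholds.
#' @param f_max,genotype_prior,conc_max_mult Model priors (see
#'   [model_config()]).
#' @param chains,adapt_iters,burn_in,sampling_iters MCMC schedule.
#' @param engine `"MCMC"` or `"QUADRATURE"`.
#' @param grid_n_f,grid_n_conc Quadrature grid resolutions.
#' @param seed Integer seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(droplet_volume = 8.5e-4, min_ff = 0.02,
                       min_paternal_droplets = 10L, max_ntc_positive = 0L,
                       p_hom_call = 0.95, p_het_call = 0.05, f_max = 0.5,
                       genotype_prior = 0.5, conc_max_mult = 5,
                       chains = 4L, adapt_iters = 1000L, burn_in = 10000L,
                       sampling_iters = 50000L,
                       engine = c("MCMC", "QUADRATURE"),
                       grid_n_f = 201L, grid_n_conc = 257L, seed = 1L) {
  engine <- match.arg(engine)
  cfg <- list(droplet_volume = droplet_volume, min_ff = min_ff,
              min_paternal_droplets = as.integer(min_paternal_droplets),
              max_ntc_positive = as.integer(max_ntc_positive),
              p_hom_call = p_hom_call, p_het_call = p_het_call,
              f_max = f_max, genotype_prior = genotype_prior,
              conc_max_mult = conc_max_mult, chains = as.integer(chains),
              adapt_iters = as.integer(adapt_iters),
              burn_in = as.integer(burn_in),
              sampling_iters = as.integer(sampling_iters), engine = engine,
              grid_n_f = as.integer(grid_n_f),
              grid_n_conc = as.integer(grid_n_conc), seed = as.integer(seed))
  # constructors validate the constraints
  call_thresholds(cfg$p_hom_call, cfg$p_het_call)
  model_config(f_max = cfg$f_max, genotype_prior = cfg$genotype_prior,
               conc_max_mult = cfg$conc_max_mult)
  mcmc_config(cfg$chains, cfg$adapt_iters, cfg$burn_in, cfg$sampling_iters,
              cfg$seed)
  stopifnot(droplet_volume > 0, min_ff >= 0, min_paternal_droplets >= 0)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys are exactly the arguments of [run_config()]; unknown keys are
#' errors, so a typo in a threshold cannot pass silently.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (known keys: ", paste(known, collapse = ", "), ")")
  do.call(run_config, vals)
}

# merge one sample's wells of a given assay role into channel_counts per role
.merge_sample_channels <- function(rows) {
  out <- lapply(split(rows, rows$channel_role), merge_wells)
  out[lengths(out) > 0]
}

#' Run the full calling pipeline on a well table
#'
#' Executes, per the clinical workflow: NTC contamination checks per assay,
#' replicate-well merging, gDNA-control bias calibration per variant assay,
#' fetal-fraction estimation and QC gating, posterior inference with the
#' chosen engine (QC-passing samples only), per-sample genotype calls and
#' per-pregnancy resolution with follow-up-sample logic. Samples missing an
#' assay are skipped with a logged reason, never a crash; every excluded
#' sample appears in the report with a machine-readable reason code.
#'
#' @param well_table A validated well table data frame (or a CSV path).
#' @param config A [run_config].
#' @param out_dir Optional directory for report files
#'   (`sample_calls.csv`, `pregnancy_results.csv`, `run_log.txt`).
#' @return An object of class `pipeline_result`: `sample_calls` and
#'   `pregnancy_results` data frames, the `posteriors` list, and the run
#'   `log`.
#' @export
run_pipeline <- function(well_table, config = run_config(), out_dir = NULL) {
  if (is.character(well_table)) well_table <- read_well_table(well_table)
  tab <- validate_well_table(well_table)
  stopifnot(inherits(config, "run_config"))
  log <- c(sprintf("run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("engine: %s, seed: %d", config$engine, config$seed))

  # NTC contamination check per assay
  ntc_rows <- tab[tab$assay_role == "NTC", , drop = FALSE]
  ntc_by_assay <- lapply(split(ntc_rows, ntc_rows$assay_id), check_ntc,
                         max_positive = config$max_ntc_positive)
  for (aid in names(ntc_by_assay)) {
    flag <- ntc_by_assay[[aid]]
    log <- c(log, sprintf("NTC check assay %s: %s%s", aid,
                          if (flag$pass) "pass" else "FAIL",
                          if (length(flag$offending_wells))
                            paste0(" (wells ",
                                   paste(flag$offending_wells, collapse = ","), ")")
                          else ""))
  }

  # gDNA-control bias calibration per assay
  gdna_rows <- tab[tab$assay_role == "GDNA_CONTROL", , drop = FALSE]
  bias_by_assay <- list()
  for (aid in unique(gdna_rows$assay_id)) {
    ch <- .merge_sample_channels(gdna_rows[gdna_rows$assay_id == aid, ])
    if (all(c("REF_ALLELE", "VAR_ALLELE") %in% names(ch))) {
      b <- tryCatch(calibrate_bias(ch$REF_ALLELE, ch$VAR_ALLELE,
                                   config$droplet_volume),
                    error = function(e) NA_real_)
      if (is.na(b)) {
        log <- c(log, sprintf("assay %s: gDNA bias calibration failed, using 1.0", aid))
      } else {
        bias_by_assay[[aid]] <- b
        log <- c(log, sprintf("assay %s: gDNA control bias %.4f", aid, b))
      }
    }
  }

  samp_tab <- tab[tab$assay_role %in% c("VARIANT", "FETAL_FRACTION"), ,
                  drop = FALSE]
  sample_ids <- unique(samp_tab$sample_id)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, length(sample_ids))

  calls <- list(); posteriors <- list(); rows <- list()
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    srows <- samp_tab[samp_tab$sample_id == sid, , drop = FALSE]
    vrows <- srows[srows$assay_role == "VARIANT", , drop = FALSE]
    frows <- srows[srows$assay_role == "FETAL_FRACTION", , drop = FALSE]
    preg <- srows$pregnancy_id[1]
    gest <- srows$gestation_weeks[1]
    base <- data.frame(pregnancy_id = preg, sample_id = sid,
                       gestation_weeks = gest, f_hat = NA_real_,
                       paternal_droplets = NA_integer_, p_hom = NA_real_,
                       qc_reasons = "", call = NA_character_,
                       stringsAsFactors = FALSE)

    vch <- .merge_sample_channels(vrows)
    fch <- .merge_sample_channels(frows)
    allelic <- all(c("REF_ALLELE", "VAR_ALLELE") %in% names(vch))
    cnv <- all(c("CNV_TARGET", "CNV_REFERENCE_LOCUS") %in% names(vch))
    if (!(allelic || cnv) ||
        !all(c("MATERNAL_ALLELE", "PATERNAL_ALLELE") %in% names(fch))) {
      log <- c(log, sprintf("sample %s: skipped, missing assay channels", sid))
      base$qc_reasons <- "MISSING_ASSAY"
      base$call <- "QC_FAIL"
      rows[[sid]] <- base
      calls[[sid]] <- structure(list(sample_id = sid, call = "QC_FAIL",
                                     p_hom = NA_real_, f_hat = NA_real_,
                                     reasons = "MISSING_ASSAY"),
                                class = "genotype_call")
      next
    }

    ff_mode <- if ("ff_mode" %in% names(frows) && !is.na(frows$ff_mode[1]) &&
                   nzchar(frows$ff_mode[1]))
      frows$ff_mode[1] else "OPPOSITE_HOMOZYGOTE_SNP"
    fetal_sex <- if ("fetal_sex" %in% names(srows)) frows$fetal_sex[1]
                 else NA_character_
    ffobs <- ff_assay_observation(fch$MATERNAL_ALLELE, fch$PATERNAL_ALLELE,
                                  mode = ff_mode, fetal_sex = fetal_sex)
    variant <- if (cnv) list(target = vch$CNV_TARGET,
                             ref_locus = vch$CNV_REFERENCE_LOCUS)
               else list(ref = vch$REF_ALLELE, var = vch$VAR_ALLELE)
    obs <- sample_observation(sid, variant, ffobs, pregnancy_id = preg,
                              droplet_volume = config$droplet_volume,
                              assay_mode = if (cnv) "CNV_DELETION" else "ALLELIC",
                              gestation_weeks = gest)

    ff <- estimate_fetal_fraction(ffobs, config$droplet_volume)
    sample_assays <- unique(srows$assay_id)
    ntc_fail <- any(vapply(ntc_by_assay[intersect(names(ntc_by_assay),
                                                  sample_assays)],
                           function(x) !x$pass, TRUE))
    ntc_flag <- list(pass = !isTRUE(ntc_fail))
    qc <- qc_sample(ff, ntc = ntc_flag, min_ff = config$min_ff,
                    min_paternal_droplets = config$min_paternal_droplets)

    bias <- if (!cnv && vrows$assay_id[1] %in% names(bias_by_assay))
      bias_by_assay[[vrows$assay_id[1]]] else 1
    mcfg <- model_config(f_max = config$f_max,
                         genotype_prior = config$genotype_prior,
                         bias = bias, conc_max_mult = config$conc_max_mult)

    post <- NULL
    if (qc$pass) {
      post <- if (config$engine == "QUADRATURE") {
        quadrature_posterior(obs, mcfg, grid = list(n_f = config$grid_n_f,
                                                    n_conc = config$grid_n_conc))
      } else {
        run_mcmc(obs, mcfg,
                 mcmc_config(config$chains, config$adapt_iters,
                             config$burn_in, config$sampling_iters,
                             seed = sample_seeds[i]),
                 keep_draws = FALSE)
      }
      posteriors[[sid]] <- post
    }
    cl <- call_genotype(post, qc,
                        call_thresholds(config$p_hom_call, config$p_het_call),
                        sample_id = sid)
    calls[[sid]] <- cl
    base$f_hat <- ff$f_hat
    base$paternal_droplets <- ff$paternal_positive_droplets
    base$p_hom <- cl$p_hom
    base$qc_reasons <- paste(qc$reasons, collapse = ";")
    base$call <- cl$call
    rows[[sid]] <- base
    log <- c(log, sprintf("sample %s: f_hat=%.4f, QC %s, call %s", sid,
                          ff$f_hat, if (qc$pass) "pass" else "fail", cl$call))
  }

  sample_calls <- do.call(rbind, rows)
  rownames(sample_calls) <- NULL

  preg_rows <- list()
  for (pid in unique(sample_calls$pregnancy_id)) {
    idx <- which(sample_calls$pregnancy_id == pid)
    gw <- sample_calls$gestation_weeks[idx]
    pr <- tryCatch(
      evaluate_pregnancy(calls[sample_calls$sample_id[idx]],
                         gestation_weeks = if (all(is.na(gw))) NULL else gw,
                         pregnancy_id = pid),
      error = function(e) e)
    if (inherits(pr, "error")) {
      log <- c(log, sprintf("pregnancy %s: CONFLICTING_CALLS (%s)", pid,
                            conditionMessage(pr)))
      preg_rows[[pid]] <- data.frame(pregnancy_id = pid,
                                     final_call = "UNRESOLVED",
                                     n_samples = length(idx),
                                     n_samples_used = length(idx),
                                     reason = "CONFLICTING_CALLS",
                                     stringsAsFactors = FALSE)
    } else {
      reason <- if (pr$final_call == "UNRESOLVED") "NO_CONCLUSIVE_SAMPLE" else ""
      preg_rows[[pid]] <- data.frame(pregnancy_id = pid,
                                     final_call = pr$final_call,
                                     n_samples = length(idx),
                                     n_samples_used = pr$n_samples_used,
                                     reason = reason, stringsAsFactors = FALSE)
      log <- c(log, sprintf("pregnancy %s: %s (sample %d of %d)", pid,
                            pr$final_call, pr$n_samples_used, length(idx)))
    }
  }
  pregnancy_results <- do.call(rbind, preg_rows)
  rownames(pregnancy_results) <- NULL
  sample_calls$final_call <- pregnancy_results$final_call[
    match(sample_calls$pregnancy_id, pregnancy_results$pregnancy_id)]

  res <- structure(list(sample_calls = sample_calls,
                        pregnancy_results = pregnancy_results,
                        posteriors = posteriors, log = log,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sample_calls, file.path(out_dir, "sample_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(pregnancy_results,
                     file.path(out_dir, "pregnancy_results.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d samples, %d pregnancies (engine %s)\n",
              nrow(x$sample_calls), nrow(x$pregnancy_results),
              x$config$engine))
  print(table(final_call = x$pregnancy_results$final_call))
  invisible(x)
}
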