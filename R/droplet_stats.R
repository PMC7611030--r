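#' Pooled droplet counts for one sample/assay/channel
#'
#' Lightweight container for positive and total accepted droplet counts,
#' possibly merged across replicate wells of the same sample, assay and
#' fluorescence channel.
#'
#' @param k Number of positive droplets (nonnegative integer).
#' @param n Total accepted droplets (positive integer, `k <= n`).
#' @param n_wells Number of wells the counts were pooled over.
#' @return An object of class `channel_counts` with elements `k`, `n`,
#'   `n_wells`.
#' @examples
#' channel_counts(12, 29000, n_wells = 2)
#' @export
channel_counts <- function(k, n, n_wells = 1L) {
  k <- as.integer(k); n <- as.integer(n); n_wells <- as.integer(n_wells)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n))
    stop("k and n must be single non-missing integers")
  if (n <= 0L) stop("total accepted droplets n must be > 0")
  if (k < 0L || k > n) stop("positive droplets k must satisfy 0 <= k <= n")
  if (n_wells < 1L) stop("n_wells must be >= 1")
  structure(list(k = k, n = n, n_wells = n_wells), class = "channel_counts")
}

#' @export
print.channel_counts <- function(x, ...) {
  cat(sprintf("<channel_counts> k = %d / n = %d positive droplets (%d well%s)\n",
              x$k, x$n, x$n_wells, if (x$n_wells > 1L) "s" else ""))
  invisible(x)
}

# channel roles recognised in well tables
.channel_roles <- c("REF_ALLELE", "VAR_ALLELE", "MATERNAL_ALLELE",
                    "PATERNAL_ALLELE", "CNV_TARGET", "CNV_REFERENCE_LOCUS")

#' Merge replicate wells into pooled channel counts
#'
#' Sums positive and total droplet counts over replicate wells that measured
#' the same sample, assay and channel. Merging is plain addition: droplets are
#' independent partitions, so pooled counts carry the combined information.
#'
#' @param wells A data frame with one row per well, containing at least the
#'   columns `positive` and `total`; if `sample_id`, `assay_id` or
#'   `channel_role` columns are present they must be constant across rows.
#' @return A [channel_counts] object with `k = sum(positive)`,
#'   `n = sum(total)`, `n_wells = nrow(wells)`.
#' @examples
#' wells <- data.frame(positive = c(5, 7), total = c(15000, 14000))
#' merge_wells(wells)
#' @export
merge_wells <- function(wells) {
  if (!is.data.frame(wells) || nrow(wells) == 0L)
    stop("merge_wells() needs a non-empty data frame of wells")
  if (!all(c("positive", "total") %in% names(wells)))
    stop("wells must have 'positive' and 'total' columns")
  for (col in c("sample_id", "assay_id", "channel_role")) {
    if (col %in% names(wells) && length(unique(wells[[col]])) > 1L)
      stop(sprintf("cannot merge wells with mixed %s: %s", col,
                   paste(unique(wells[[col]]), collapse = ", ")))
  }
  if (any(wells$positive < 0) || any(wells$total <= 0) ||
      any(wells$positive > wells$total))
    stop("each well must satisfy 0 <= positive <= total, total > 0")
  channel_counts(sum(wells$positive), sum(wells$total), nrow(wells))
}

# Wilson 95% score interval on a binomial proportion; the standard interval
# behind prop.test(correct = FALSE)
.wilson_ci <- function(k, n, conf_level = 0.95) {
  ci <- stats::prop.test(k, n, correct = FALSE,
                         conf.level = conf_level)$conf.int
  c(low = max(0, ci[1]), high = min(1, ci[2]))
}

#' Estimate target concentration from droplet counts
#'
#' Inverts the Poisson partition model of digital PCR: if a fraction
#' `p = k/n` of droplets is positive, the mean number of target copies per
#' droplet is `-log(1 - p)` and the concentration is `-log(1 - p) / v` copies
#' per microliter of reaction, where `v` is the droplet volume. The 95% CI is
#' a Wilson score interval on `p` pushed through the same monotone map.
#'
#' @param counts A [channel_counts] object.
#' @param droplet_volume Droplet volume in microliters (default `8.5e-4`,
#'   i.e. 0.85 nL).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `concentration_estimate` with elements
#'   `lambda`, `ci_low`, `ci_high` (copies/uL) and `droplet_volume`.
#' @examples
#' estimate_concentration(channel_counts(1000, 20000))
#' @export
estimate_concentration <- function(counts, droplet_volume = 8.5e-4,
                                   conf_level = 0.95) {
  stopifnot(inherits(counts, "channel_counts"))
  if (droplet_volume <= 0) stop("droplet_volume must be > 0")
  if (counts$k == counts$n)
    stop("all droplets positive: channel saturated, concentration unquantifiable")
  p <- counts$k / counts$n
  lam <- -log1p(-p) / droplet_volume
  if (counts$k == 0L) {
    ci <- c(low = 0, high = .wilson_ci(0L, counts$n, conf_level)[["high"]])
  } else {
    ci <- .wilson_ci(counts$k, counts$n, conf_level)
  }
  ci_high <- if (ci[["high"]] >= 1) Inf else -log1p(-ci[["high"]]) / droplet_volume
  structure(list(lambda = lam,
                 ci_low = -log1p(-ci[["low"]]) / droplet_volume,
                 ci_high = ci_high,
                 droplet_volume = droplet_volume),
            class = "concentration_estimate")
}

#' @export
print.concentration_estimate <- function(x, ...) {
  cat(sprintf("<concentration_estimate> %.4g copies/uL (95%% CI %.4g-%.4g)\n",
              x$lambda, x$ci_low, x$ci_high))
  invisible(x)
}

#' Fractional abundance of one channel's target over two channels
#'
#' Computes `lambda_a / (lambda_a + lambda_b)` from the Poisson-corrected
#' concentrations of a duplexed assay's two channels. The interval is
#' conservative: the fraction is evaluated at paired CI extremes
#' (low-a with high-b, and vice versa).
#'
#' @param a,b [channel_counts] for the two channels (same reaction volume).
#' @param droplet_volume Droplet volume in microliters.
#' @return An object of class `fraction_estimate` with `frac`, `ci_low`,
#'   `ci_high` in `[0, 1]`.
#' @examples
#' fractional_abundance(channel_counts(1100, 20000), channel_counts(900, 20000))
#' @export
fractional_abundance <- function(a, b, droplet_volume = 8.5e-4) {
  ca <- estimate_concentration(a, droplet_volume)
  cb <- estimate_concentration(b, droplet_volume)
  if (ca$lambda + cb$lambda == 0)
    stop("both channels have zero positives: fractional abundance undefined")
  frac <- ca$lambda / (ca$lambda + cb$lambda)
  lo <- if (ca$ci_low + cb$ci_high == 0) 0 else ca$ci_low / (ca$ci_low + cb$ci_high)
  hi <- if (is.infinite(cb$ci_low) || ca$ci_high + cb$ci_low == 0) 1
        else ca$ci_high / (ca$ci_high + cb$ci_low)
  if (is.infinite(ca$ci_high)) hi <- 1
  structure(list(frac = frac, ci_low = lo, ci_high = min(hi, 1)),
            class = "fraction_estimate")
}

#' @export
print.fraction_estimate <- function(x, ...) {
  cat(sprintf("<fraction_estimate> %.4f (95%% CI %.4f-%.4f)\n",
              x$frac, x$ci_low, x$ci_high))
  invisible(x)
}

#' Check no-template control wells for contamination
#'
#' A template-free control well with positive droplets above `max_positive`
#' indicates contamination of the assay run.
#'
#' @param ntc_wells Data frame of NTC wells with `positive` and `total`
#'   columns (and optionally `well_id`); may have zero rows.
#' @param max_positive Maximum tolerated positive droplets per NTC well
#'   (default 0: any positive droplet fails the check).
#' @return A list with `pass` (logical), `offending_wells` (character vector)
#'   and `warning` (`NA` or a message, e.g. when no NTC wells were supplied).
#' @examples
#' check_ntc(data.frame(well_id = "N01", positive = 0, total = 15000))
#' @export
check_ntc <- function(ntc_wells, max_positive = 0L) {
  if (is.null(ntc_wells) || nrow(ntc_wells) == 0L) {
    return(list(pass = TRUE, offending_wells = character(0),
                warning = "no NTC wells supplied; contamination not assessed"))
  }
  bad <- ntc_wells$positive > max_positive
  ids <- if ("well_id" %in% names(ntc_wells)) as.character(ntc_wells$well_id)
         else as.character(seq_len(nrow(ntc_wells)))
  list(pass = !any(bad), offending_wells = ids[bad], warning = NA_character_)
}
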