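# shared fixture builders: everything is generated in code at test time

cc <- function(k, n = 20000L, wells = 1L) channel_counts(k, n, wells)

# a sample_observation built directly from four channel counts
make_obs <- function(k_ref, k_var, k_pat, k_mat, n = 60000L,
                     assay_mode = "ALLELIC", droplet_volume = 8.5e-4) {
  variant <- if (assay_mode == "CNV_DELETION")
    list(target = cc(k_ref, n), ref_locus = cc(k_var, n))
  else list(ref = cc(k_ref, n), var = cc(k_var, n))
  sample_observation("s1", variant,
                     ff_assay_observation(cc(k_mat, n), cc(k_pat, n)),
                     droplet_volume = droplet_volume,
                     assay_mode = assay_mode)
}

# chi-square posterior calibration check: among samples binned by p_hom, the
# observed count of truly homozygous fetuses should match the summed
# posterior probabilities up to binomial noise
calibration_pvalue <- function(p_hom, is_hom, breaks = seq(0, 1, by = 0.2)) {
  bin <- cut(p_hom, breaks, include.lowest = TRUE)
  stat <- 0; df <- 0
  for (b in levels(bin)) {
    idx <- bin == b
    if (!any(idx)) next
    e <- sum(p_hom[idx])
    v <- sum(p_hom[idx] * (1 - p_hom[idx]))
    if (v < 1e-3) next  # degenerate bin: all mass at 0 or 1
    stat <- stat + (sum(is_hom[idx]) - e)^2 / v
    df <- df + 1
  }
  stats::pchisq(stat, df, lower.tail = FALSE)
}
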