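# shared fixtures built in code

# compact panel: enough gene-region SNPs for phasing plus the auxiliary classes
small_panel <- function(n_dmd = 120, n_chrx = 10, n_chry = 10, n_auto = 60,
                        seed = 101) {
  build_panel(panel_config(n_dmd_flank = n_dmd, n_chrx = n_chrx,
                           n_chry = n_chry, n_autosomal = n_auto),
              seed = seed)
}

# hand-built genotype table (hard_genotypes layout) from snp_id -> dose
gt_table <- function(snp_id, dose, depth = 200) {
  data.frame(snp_id = snp_id, depth = depth, alt_fraction = dose,
             dose = dose, stringsAsFactors = FALSE)
}

# hand-built dosage series for direct Bayes-factor / CBS input
make_series <- function(pos, type_class, tracked_count, depth,
                        af_gdna = 0.5) {
  af_cf <- tracked_count / depth
  structure(data.frame(snp_id = sprintf("s%04d", seq_along(pos)), pos = pos,
                       type_class = type_class, af_cfdna = af_cf,
                       af_gdna = af_gdna, dc = af_cf - af_gdna,
                       tracked_count = tracked_count, depth_cfdna = depth,
                       stringsAsFactors = FALSE),
            n_dropped = 0L, class = c("dosage_series", "data.frame"))
}

# synthetic oriented dosage series as a null / changepoint CBS input:
# per-SNP dc drawn as binomial allele-frequency noise around the given means
noisy_series <- function(means, depth = 300) {
  n <- length(means)
  k <- rbinom(n, depth, 0.5 + means)
  make_series(pos = seq_len(n) * 1000L, type_class = rep("type1", n),
              tracked_count = k, depth = depth)
}
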