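#' Depth quality control for one sequencing sample
#'
#' Computes the mean depth of a sample over the panel SNPs and compares it to
#' the kind-specific floor: 30x for genomic DNA, 70x for plasma cfDNA.  A
#' sample below the floor must be re-sequenced before analysis.
#'
#' @param counts count table (one or more samples).
#' @param sample_kind `"gdna"` or `"cfdna"`.
#' @param sample_id optional: restrict `counts` to this sample.
#' @param panel optional panel; when given, SNPs absent from the count table
#'   contribute zero depth.
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"depth_qc"`: `sample_id`, `mean_depth`,
#'   `fraction_ge_30x`, `pass`, `action` (`"ok"` or `"resequence"`).
#' @export
#' @examples
#' ct <- data.frame(sample_id = "s1", snp_id = c("a", "b"),
#'                  ref_count = c(40L, 60L), alt_count = c(45L, 55L))
#' depth_qc(ct, "gdna")$action
depth_qc <- function(counts, sample_kind = c("gdna", "cfdna"),
                     sample_id = NULL, panel = NULL,
                     thresholds = nipd_thresholds()) {
  sample_kind <- match.arg(sample_kind)
  if (!is.null(sample_id)) counts <- counts[counts$sample_id == sample_id, ]
  if (nrow(counts) == 0) stop("empty count table")
  depth <- counts$ref_count + counts$alt_count
  n_loci <- if (is.null(panel)) nrow(counts) else nrow(panel)
  mean_depth <- sum(depth) / n_loci
  floor <- if (sample_kind == "gdna") thresholds$gdna_min_depth
           else thresholds$cfdna_min_depth
  pass <- mean_depth >= floor
  structure(list(sample_id = counts$sample_id[1], sample_kind = sample_kind,
                 mean_depth = mean_depth,
                 fraction_ge_30x = sum(depth >= 30) / n_loci,
                 pass = pass,
                 action = if (pass) "ok" else "resequence"),
            class = "depth_qc")
}

#' Estimate the fetal fraction from autosomal cfDNA counts
#'
#' At autosomal loci where the mother is homozygous but the fetus carries a
#' paternal allele the mother lacks, the fetal-specific allele depth `a` and
#' the shared allele depth `b` give a per-locus ratio `a / (a + b)` with
#' expectation f/2 (the fetus is heterozygous there).  Loci below 100x depth
#' or failing the base-quality flag are removed.  With paternal genotypes the
#' qualifying loci are mother-homozygous / father-homozygous-opposite (the
#' fetus is then heterozygous by necessity); without a father, loci where the
#' mother is homozygous and the cfDNA minor-allele fraction falls in
#' (0.5%, 20%) are taken as fetal-informative.
#'
#' The returned `f` is the total fetal proportion of cfDNA,
#' `2 * sum(a) / sum(a + b)` pooled over qualifying loci (mode
#' `"doubled"`/`"pooled"`).  Mode `"as_printed"` reports the undoubled ratio;
#' `aggregate = "mean"` averages per-locus ratios instead of pooling counts.
#'
#' @param cfdna_counts cfDNA count table (single sample).
#' @param maternal_genotypes,paternal_genotypes hard-call tables from
#'   [hard_genotypes()] (`paternal_genotypes` may be `NULL`).
#' @param panel the SNP panel.
#' @param mode `"doubled"` (default) or `"as_printed"`.
#' @param aggregate `"pooled"` (default) or `"mean"`.
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"fetal_fraction"`: `f`, `n_informative_loci`,
#'   `a`, `b` (per-locus depths), `mode`, `action` (`"ok"` or `"redraw"`
#'   when `f` is below 1%).
#' @export
estimate_fetal_fraction <- function(cfdna_counts, maternal_genotypes,
                                    paternal_genotypes = NULL, panel,
                                    mode = c("doubled", "as_printed"),
                                    aggregate = c("pooled", "mean"),
                                    thresholds = nipd_thresholds()) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  auto <- panel[panel$region_class == "autosomal", ]
  if (nrow(auto) == 0) stop("panel has no autosomal SNPs")

  ct <- cfdna_counts[cfdna_counts$snp_id %in% auto$snp_id, ]
  ct <- ct[!duplicated(ct$snp_id), ]
  depth <- ct$ref_count + ct$alt_count
  ok <- depth >= thresholds$snp_min_depth &
    (is.null(ct$base_quality_ok) | ct$base_quality_ok)
  ct <- ct[ok, ]; depth <- depth[ok]

  mg <- maternal_genotypes[match(ct$snp_id, maternal_genotypes$snp_id), ]
  m_hom <- !is.na(mg$dose) & mg$dose %in% c(0, 1)

  if (!is.null(paternal_genotypes)) {
    pg <- paternal_genotypes[match(ct$snp_id, paternal_genotypes$snp_id), ]
    keep <- m_hom & !is.na(pg$dose) & pg$dose %in% c(0, 1) &
      pg$dose == 1 - mg$dose
    ct <- ct[keep, ]; mg <- mg[keep, ]
    # fetal-specific allele = the paternal allele the mother lacks
    a <- ifelse(mg$dose == 0, ct$alt_count, ct$ref_count)
    b <- ifelse(mg$dose == 0, ct$ref_count, ct$alt_count)
  } else {
    minor <- pmin(ct$ref_count, ct$alt_count)
    frac <- minor / pmax(depth, 1)
    keep <- m_hom & frac > 0.005 & frac < 0.20
    ct <- ct[keep, ]; mg <- mg[keep, ]
    a <- ifelse(mg$dose == 0, ct$alt_count, ct$ref_count)
    b <- ifelse(mg$dose == 0, ct$ref_count, ct$alt_count)
  }
  if (length(a) == 0)
    stop("no qualifying loci for fetal-fraction estimation")

  ratio <- if (aggregate == "pooled") sum(a) / sum(a + b)
           else mean(a / (a + b))
  f <- if (mode == "doubled") 2 * ratio else ratio
  structure(list(f = f, n_informative_loci = length(a), a = a, b = b,
                 mode = mode, aggregate = aggregate,
                 action = if (f < thresholds$ff_min) "redraw" else "ok"),
            class = "fetal_fraction")
}

#' Call fetal sex from the chrY depth ratio
#'
#' The ratio of mean depth at chrY sites to mean depth at autosomal panel
#' SNPs in maternal plasma is essentially zero for a female fetus and scales
#' with the fetal fraction for a male fetus.  A ratio strictly below 0.3%
#' calls a female fetus; otherwise male.
#'
#' @param cfdna_counts cfDNA count table (single sample).
#' @param panel the SNP panel (must contain chrY sites and autosomal SNPs).
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"sex_call"`: `chry_ratio`, `sex`.
#' @export
call_fetal_sex <- function(cfdna_counts, panel,
                           thresholds = nipd_thresholds()) {
  ys <- panel$snp_id[panel$region_class == "chrY_site"]
  as <- panel$snp_id[panel$region_class == "autosomal"]
  if (length(ys) == 0 || length(as) == 0)
    stop("panel must contain chrY sites and autosomal SNPs")
  dep <- function(ids) {
    ct <- cfdna_counts[cfdna_counts$snp_id %in% ids, ]
    sum(ct$ref_count + ct$alt_count) / length(ids)
  }
  auto_depth <- dep(as)
  if (auto_depth <= 0) stop("zero autosomal depth in cfDNA sample")
  ratio <- dep(ys) / auto_depth
  structure(list(chry_ratio = ratio,
                 sex = if (ratio < thresholds$chry) "female" else "male"),
            class = "sex_call")
}
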