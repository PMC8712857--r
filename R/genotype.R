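#' Hard genotype calls from gDNA allele counts
#'
#' Converts per-SNP allele counts of a genomic DNA sample into dose calls:
#' alternate-allele fraction below 0.15 is homozygous reference (dose 0),
#' above 0.85 homozygous alternate (dose 1), otherwise heterozygous
#' (dose 0.5).  SNPs below the depth floor get `NA` doses.  Hemizygous male
#' X genotypes fall out naturally as dose 0/1.
#'
#' @param counts count table.
#' @param sample_id optional: restrict to one sample.
#' @param min_depth minimum depth for a call (default 30).
#' @param hom_ref_max,hom_alt_min allele-fraction cut points.
#' @return A `data.frame` with columns `snp_id`, `depth`, `alt_fraction`,
#'   `dose`.
#' @export
hard_genotypes <- function(counts, sample_id = NULL, min_depth = 30,
                           hom_ref_max = 0.15, hom_alt_min = 0.85) {
  if (!is.null(sample_id)) counts <- counts[counts$sample_id == sample_id, ]
  if (nrow(counts) == 0) stop("empty count table")
  depth <- counts$ref_count + counts$alt_count
  af <- ifelse(depth > 0, counts$alt_count / depth, NA_real_)
  dose <- ifelse(af < hom_ref_max, 0, ifelse(af > hom_alt_min, 1, 0.5))
  dose[depth < min_depth] <- NA_real_
  data.frame(snp_id = counts$snp_id, depth = depth, alt_fraction = af,
             dose = dose, stringsAsFactors = FALSE)
}
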