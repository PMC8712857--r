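#' Phase the maternal haplotypes from pedigree genotypes
#'
#' Builds the two maternal haplotypes over the gene-region (`dmd_flank`)
#' SNPs at which the mother is heterozygous, using Mendelian transmission to
#' a phasing relative.  Hap1 is, by definition, the maternal haplotype that
#' carries the pathogenic variant:
#' \itemize{
#'   \item an affected male proband is hemizygous on the X, so his allele at
#'     each maternal-heterozygous SNP is the Hap1 allele;
#'   \item a carrier daughter's maternally derived allele (resolved against
#'     the father's hemizygous X genotype) is the Hap1 allele;
#'   \item an unaffected daughter's maternally derived allele is the Hap2
#'     allele; Hap1 is the complement and the assignment is flagged as
#'     swapped (`swap_applied`).
#' }
#' SNPs whose genotypes are Mendelian-inconsistent (e.g. a heterozygous call
#' on a male X, or a daughter lacking the paternal allele) are dropped; a
#' drop rate above 5% of candidate SNPs raises a sample-swap warning.
#'
#' @param maternal_genotypes hard-call table for the mother
#'   ([hard_genotypes()]).
#' @param relative_genotypes hard-call table for the phasing relative.
#' @param relative_role `"proband"` (affected male) or `"daughter"`.
#' @param paternal_genotypes hard-call table for the father; required when
#'   phasing through a daughter.
#' @param daughter_status `"unaffected"` or `"carrier"`; ignored for a
#'   proband.
#' @param panel the SNP panel.
#' @return A `data.frame` of class `"phased_haplotypes"` with columns
#'   `snp_id`, `pos`, `hap1_dose`, `hap2_dose`, `hap1_allele`,
#'   `hap2_allele`, and attributes `phasing_source`, `swap_applied`,
#'   `n_candidate`, `n_dropped`.
#' @export
phase_maternal <- function(maternal_genotypes, relative_genotypes,
                           relative_role = c("proband", "daughter"),
                           paternal_genotypes = NULL,
                           daughter_status = c("unaffected", "carrier"),
                           panel) {
  relative_role <- match.arg(relative_role)
  daughter_status <- match.arg(daughter_status)

  reg <- panel[panel$region_class == "dmd_flank", ]
  mg <- maternal_genotypes[match(reg$snp_id, maternal_genotypes$snp_id), ]
  het <- !is.na(mg$dose) & mg$dose == 0.5
  reg <- reg[het, ]
  if (nrow(reg) == 0) stop("mother is heterozygous at no gene-region SNP")

  rel <- relative_genotypes[match(reg$snp_id, relative_genotypes$snp_id), ]

  if (relative_role == "proband") {
    hemiz_ok <- !is.na(rel$dose) & rel$dose %in% c(0, 1)
    hap1 <- rel$dose
    swap <- FALSE
    source <- "proband"
    keep <- hemiz_ok
    n_inconsistent <- sum(!is.na(rel$dose) & rel$dose == 0.5)
  } else {
    if (is.null(paternal_genotypes))
      stop("phasing through a daughter requires paternal X genotypes")
    pat <- paternal_genotypes[match(reg$snp_id, paternal_genotypes$snp_id), ]
    p_ok <- !is.na(pat$dose) & pat$dose %in% c(0, 1)
    # maternal transmitted allele: daughter dose = (m + p) / 2  =>  m = 2d - p
    m <- 2 * rel$dose - pat$dose
    m_ok <- p_ok & !is.na(m) & m %in% c(0, 1)
    if (daughter_status == "carrier") {
      hap1 <- m
      swap <- FALSE
      source <- "daughter_carrier"
    } else {
      hap1 <- 1 - m  # transmitted allele sits on Hap2; mother is het
      swap <- TRUE
      source <- "daughter_unaffected"
    }
    keep <- m_ok
    n_inconsistent <- sum(p_ok & !is.na(m) & !(m %in% c(0, 1)))
  }

  n_candidate <- nrow(reg)
  if (n_inconsistent > 0.05 * n_candidate)
    warning("Mendelian inconsistency at ", n_inconsistent, " of ",
            n_candidate, " SNPs (> 5%): possible sample swap")

  reg <- reg[keep, ]; hap1 <- hap1[keep]
  hap2 <- 1 - hap1
  out <- data.frame(
    snp_id = reg$snp_id, pos = reg$pos,
    hap1_dose = hap1, hap2_dose = hap2,
    hap1_allele = ifelse(hap1 == 1, reg$alt, reg$ref),
    hap2_allele = ifelse(hap2 == 1, reg$alt, reg$ref),
    stringsAsFactors = FALSE)
  out <- out[order(out$pos), ]
  rownames(out) <- NULL
  structure(out, phasing_source = source, swap_applied = swap,
            n_candidate = n_candidate, n_dropped = sum(!keep),
            class = c("phased_haplotypes", "data.frame"))
}

#' Classify phased SNPs into Type 1 / Type 2 informative alleles
#'
#' Type 1 alleles track Hap1 (the pathogenic maternal haplotype) and Type 2
#' alleles track Hap2.  For a male fetus every phased SNP contributes both
#' its Hap1 allele to the Type 1 set and its Hap2 allele to the Type 2 set
#' (the father's X never reaches a male fetus).  For a female fetus with
#' paternal genotypes, a SNP joins Type 1 only if its Hap1 allele equals the
#' paternal allele and Type 2 only if its Hap2 allele does: only then is the
#' fetus homozygous-equivalent for the tracked allele and the full +/- f/2
#' dosage shift expected.  For a female fetus without a father the male rule
#' is used as a fallback and the result is flagged as reduced-reliability.
#'
#' @param phased a [phase_maternal()] result.
#' @param paternal_genotypes hard-call table for the father, or `NULL`.
#' @param fetal_sex `"male"` or `"female"`.
#' @param thresholds see [nipd_thresholds()].
#' @return A `data.frame` of class `"informative_set"` with columns
#'   `snp_id`, `pos`, `type_class`, `tracked_dose`, `tracked_allele`, and
#'   attributes `n_type1`, `n_type2`, `qc_pass`, `no_father_fallback`.
#' @export
classify_informative <- function(phased, paternal_genotypes = NULL,
                                 fetal_sex = c("male", "female"),
                                 thresholds = nipd_thresholds()) {
  fetal_sex <- match.arg(fetal_sex)
  stopifnot(inherits(phased, "phased_haplotypes"))
  fallback <- FALSE

  if (fetal_sex == "female" && !is.null(paternal_genotypes)) {
    pat <- paternal_genotypes[match(phased$snp_id,
                                    paternal_genotypes$snp_id), ]
    ok <- !is.na(pat$dose) & pat$dose %in% c(0, 1)
    ph <- phased[ok, ]; pd <- pat$dose[ok]
    is_t1 <- ph$hap1_dose == pd  # biallelic: otherwise hap2 matches
    out <- data.frame(
      snp_id = ph$snp_id, pos = ph$pos,
      type_class = ifelse(is_t1, "type1", "type2"),
      tracked_dose = ifelse(is_t1, ph$hap1_dose, ph$hap2_dose),
      tracked_allele = ifelse(is_t1, ph$hap1_allele, ph$hap2_allele),
      stringsAsFactors = FALSE)
  } else {
    if (fetal_sex == "female") fallback <- TRUE
    out <- rbind(
      data.frame(snp_id = phased$snp_id, pos = phased$pos,
                 type_class = "type1", tracked_dose = phased$hap1_dose,
                 tracked_allele = phased$hap1_allele,
                 stringsAsFactors = FALSE),
      data.frame(snp_id = phased$snp_id, pos = phased$pos,
                 type_class = "type2", tracked_dose = phased$hap2_dose,
                 tracked_allele = phased$hap2_allele,
                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$pos, out$type_class), ]
  rownames(out) <- NULL
  n1 <- sum(out$type_class == "type1")
  n2 <- sum(out$type_class == "type2")
  structure(out, n_type1 = n1, n_type2 = n2,
            qc_pass = n1 >= thresholds$min_informative &&
                      n2 >= thresholds$min_informative,
            no_father_fallback = fallback,
            class = c("informative_set", "data.frame"))
}

#' QC gate on the informative-SNP counts
#'
#' Fewer than 10 Type 1 or Type 2 alleles indicates shared parental
#' haplotypes (consanguinity); haplotype-based NIPD is then unsuitable and
#' invasive diagnosis is recommended.
#'
#' @param informative an [classify_informative()] result.
#' @param thresholds see [nipd_thresholds()].
#' @return A list: `qc_pass`, `n_type1`, `n_type2`, `decision` text.
#' @export
informative_qc <- function(informative, thresholds = nipd_thresholds()) {
  n1 <- attr(informative, "n_type1")
  n2 <- attr(informative, "n_type2")
  pass <- n1 >= thresholds$min_informative &&
          n2 >= thresholds$min_informative
  list(qc_pass = pass, n_type1 = n1, n_type2 = n2,
       decision = if (pass) "ok" else
         "informative SNPs below minimum; recommend invasive diagnosis")
}
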