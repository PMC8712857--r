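#' Configuration for a simulated NIPD family
#'
#' Fixes the pedigree shape, fetal state and sequencing design of one
#' synthetic family.  Defaults reflect the clinical setting the package
#' models: mean cfDNA depth 290x, gDNA depth around 200x, fetal fraction near
#' the cohort median (6%), and a pathogenic deletion inside the exon 44-55
#' hotspot of the gene window.
#'
#' @param pedigree_shape `"complete"` (mother, father, affected proband),
#'   `"no_father"` (mother and proband), or `"no_proband_daughter"`
#'   (mother, father and a daughter used for phasing).
#' @param fetal_sex `"male"` or `"female"`.
#' @param fetal_inherits which maternal haplotype the fetus receives at the
#'   start of the X: `"hap1"` (the pathogenic one, carried by the proband)
#'   or `"hap2"`.
#' @param fetal_fraction fetal proportion of cfDNA, in (0, 0.5).
#' @param cfdna_depth,gdna_depth mean reads per SNP for the plasma and the
#'   genomic samples.
#' @param recombination_pos optional base position of a maternal crossover in
#'   the fetus; the transmitted haplotype switches source at the first SNP
#'   strictly beyond this position.
#' @param variant_interval length-2 base-position bounds of the pathogenic
#'   lesion; must lie inside the gene window of the panel in use.
#' @param daughter_status for `no_proband_daughter` pedigrees: is the
#'   phasing daughter a `"carrier"` (carries Hap1) or `"unaffected"`
#'   (carries Hap2)?
#' @param realistic_male_x if `TRUE`, a male fetus contributes one X per
#'   genome copy so the effective X fetal fraction is `f / (2 - f)`; the
#'   default (`FALSE`) applies the same +/- f/2 dosage expectation to both
#'   sexes, matching the inference model (see the methods vignette).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return A list of class `"family_config"`.
#' @export
family_config <- function(pedigree_shape = c("complete", "no_father",
                                             "no_proband_daughter"),
                          fetal_sex = c("male", "female"),
                          fetal_inherits = c("hap1", "hap2"),
                          fetal_fraction = 0.06,
                          cfdna_depth = 290, gdna_depth = 200,
                          recombination_pos = NULL,
                          variant_interval = c(31900000, 32100000),
                          daughter_status = c("unaffected", "carrier"),
                          realistic_male_x = FALSE,
                          seed = NULL) {
  pedigree_shape <- match.arg(pedigree_shape)
  fetal_sex <- match.arg(fetal_sex)
  fetal_inherits <- match.arg(fetal_inherits)
  daughter_status <- match.arg(daughter_status)
  if (!(fetal_fraction >= 0 && fetal_fraction < 0.5))
    stop("fetal_fraction must lie in [0, 0.5)")  # 0 = no fetal signal
  if (cfdna_depth < 1 || gdna_depth < 1) stop("depths must be >= 1")
  if (length(variant_interval) != 2 || variant_interval[1] > variant_interval[2])
    stop("variant_interval must be (start, end) with start <= end")
  structure(list(pedigree_shape = pedigree_shape, fetal_sex = fetal_sex,
                 fetal_inherits = fetal_inherits,
                 fetal_fraction = fetal_fraction,
                 cfdna_depth = cfdna_depth, gdna_depth = gdna_depth,
                 recombination_pos = recombination_pos,
                 variant_interval = variant_interval,
                 daughter_status = daughter_status,
                 realistic_male_x = realistic_male_x, seed = seed),
            class = "family_config")
}

# chrY background depth for samples without a Y (fraction of the mean depth);
# kept below the 0.3% sex threshold, consistent with observed female ratios
CHRY_NOISE_FLOOR <- 5e-4

#' Simulate one NIPD family: haplotypes, genotypes and read counts
#'
#' Draws parental haplotypes per SNP from the panel allele frequencies,
#' transmits them to an affected proband (always carrying maternal Hap1), an
#' optional daughter, and the fetus (with an optional crossover), and then
#' samples sequencing read counts: gDNA counts are binomial in the genotype
#' dose at Poisson per-SNP depths, and cfDNA counts are binomial in a mixture
#' of maternal dose (weight 1 - f) and fetal dose (weight f).  At a
#' maternal-heterozygous SNP where the fetus is homozygous-equivalent this
#' yields the canonical +/- f/2 expected allele-frequency shift.  chrY sites
#' receive depth proportional to f/2 for a male fetus and a small noise floor
#' otherwise.
#'
#' @param panel a panel from [build_panel()].
#' @param config a [family_config()].
#' @return An object of class `"family_sim"`: a list with `truth` (haplotype
#'   vectors, fetal sex/inheritance, `true_class`), `counts` (long-format
#'   table: `sample_id`, `snp_id`, `ref_count`, `alt_count`,
#'   `base_quality_ok`), `pedigree`, `panel` and `config`.
#' @export
#' @examples
#' pan <- build_panel(panel_config(n_dmd_flank = 60, n_chrx = 10,
#'                                 n_chry = 5, n_autosomal = 30), seed = 1)
#' sim <- simulate_family(pan, family_config(fetal_fraction = 0.1, seed = 2))
#' sim$truth$true_class
simulate_family <- function(panel, config = family_config()) {
  stopifnot(inherits(config, "family_config"))
  validate_panel(panel)
  vi <- config$variant_interval
  if (!is.null(config$recombination_pos) &&
      (config$recombination_pos < min(panel$pos[panel$chrom == "chrX"]) ||
       config$recombination_pos > max(panel$pos[panel$chrom == "chrX"])))
    stop("recombination_pos lies outside the chrX panel span")
  if (!is.null(config$seed)) set.seed(config$seed)

  is_x <- panel$region_class %in% c("dmd_flank", "chrX_common")
  is_y <- panel$region_class == "chrY_site"
  is_a <- panel$region_class == "autosomal"
  xp <- panel[is_x, ]
  xp <- xp[order(xp$pos), ]
  ap <- panel[is_a, ]

  draw_hap <- function(maf) as.integer(runif(length(maf)) < maf)
  hap1 <- stats::setNames(draw_hap(xp$maf), xp$snp_id)   # carries the variant
  hap2 <- stats::setNames(draw_hap(xp$maf), xp$snp_id)
  patX <- stats::setNames(draw_hap(xp$maf), xp$snp_id)   # father hemizygous
  m_a1 <- stats::setNames(draw_hap(ap$maf), ap$snp_id)
  m_a2 <- stats::setNames(draw_hap(ap$maf), ap$snp_id)
  p_a1 <- stats::setNames(draw_hap(ap$maf), ap$snp_id)
  p_a2 <- stats::setNames(draw_hap(ap$maf), ap$snp_id)

  # fetal maternal X haplotype, with optional crossover
  first <- if (config$fetal_inherits == "hap1") hap1 else hap2
  other <- if (config$fetal_inherits == "hap1") hap2 else hap1
  if (is.null(config$recombination_pos)) {
    fet_mx <- first
  } else {
    fet_mx <- ifelse(xp$pos <= config$recombination_pos, first, other)
    names(fet_mx) <- xp$snp_id
  }

  # class is decided by the haplotype transmitted at the variant itself
  mid <- mean(vi)
  inherits_at_variant <-
    if (is.null(config$recombination_pos) || mid <= config$recombination_pos)
      config$fetal_inherits
    else if (config$fetal_inherits == "hap1") "hap2" else "hap1"
  true_class <- if (inherits_at_variant == "hap1") {
    if (config$fetal_sex == "male") "affected" else "carrier"
  } else "normal"

  f <- config$fetal_fraction
  fet_x_dose <- if (config$fetal_sex == "male") fet_mx else (fet_mx + patX) / 2
  fet_a_dose <- (m_a1 + p_a1) / 2

  sample_counts <- function(sample_id, mean_depth, x_dose, a_dose,
                            has_y, y_mean = NULL, x_depth_factor = 1) {
    n <- nrow(panel)
    dose <- numeric(n)
    depth_mean <- rep(mean_depth, n)
    dose[is_x] <- x_dose[match(panel$snp_id[is_x], names(x_dose))]
    dose[is_a] <- a_dose[match(panel$snp_id[is_a], names(a_dose))]
    depth_mean[is_x] <- depth_mean[is_x] * x_depth_factor
    if (is.null(y_mean))
      y_mean <- if (has_y) mean_depth / 2 else mean_depth * CHRY_NOISE_FLOOR
    depth_mean[is_y] <- y_mean
    dose[is_y] <- 0  # Y sites are presence/absence: all reads counted as ref
    depth <- rpois(n, depth_mean)
    alt <- rbinom(n, depth, dose)
    data.frame(sample_id = sample_id, snp_id = panel$snp_id,
               ref_count = depth - alt, alt_count = alt,
               base_quality_ok = TRUE, stringsAsFactors = FALSE)
  }

  gd <- config$gdna_depth
  shape <- config$pedigree_shape
  blocks <- list()
  blocks$mother <- sample_counts("mother", gd, (hap1 + hap2) / 2,
                                 (m_a1 + m_a2) / 2, has_y = FALSE)
  if (shape %in% c("complete", "no_proband_daughter"))
    blocks$father <- sample_counts("father", gd, patX, (p_a1 + p_a2) / 2,
                                   has_y = TRUE, x_depth_factor = 0.5)
  if (shape %in% c("complete", "no_father"))
    blocks$proband <- sample_counts("proband", gd, hap1,
                                    (m_a2 + p_a2) / 2, has_y = TRUE,
                                    x_depth_factor = 0.5)
  if (shape == "no_proband_daughter") {
    d_hap <- if (config$daughter_status == "carrier") hap1 else hap2
    blocks$daughter <- sample_counts("daughter", gd, (d_hap + patX) / 2,
                                     (m_a2 + p_a2) / 2, has_y = FALSE)
  }

  # maternal plasma: mixture of maternal and fetal dose
  cf <- config$cfdna_depth
  cf_x_dose <- (1 - f) * (hap1 + hap2) / 2 + f * fet_x_dose
  x_factor <- 1
  if (config$fetal_sex == "male" && config$realistic_male_x) {
    # one fetal X per genome copy: fetal weight f/2, total X mass 1 - f/2
    cf_x_dose <- ((1 - f) * (hap1 + hap2) / 2 + (f / 2) * fet_mx) / (1 - f / 2)
    x_factor <- 1 - f / 2
  }
  cf_a_dose <- (1 - f) * (m_a1 + m_a2) / 2 + f * fet_a_dose
  y_mean <- if (config$fetal_sex == "male") cf * f / 2 else cf * CHRY_NOISE_FLOOR
  blocks$cfDNA <- sample_counts("cfDNA", cf, cf_x_dose, cf_a_dose,
                                has_y = FALSE, y_mean = y_mean,
                                x_depth_factor = x_factor)

  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL

  ped_row <- function(sid, father, mother, sex, aff, role)
    data.frame(family_id = "F1", sample_id = sid, father_id = father,
               mother_id = mother, sex = sex, affected = aff, role = role,
               stringsAsFactors = FALSE)
  ped <- list(ped_row("mother", "0", "0", 2L, 1L, "mother"))
  if (!is.null(blocks$father))
    ped <- c(ped, list(ped_row("father", "0", "0", 1L, 1L, "father")))
  if (!is.null(blocks$proband))
    ped <- c(ped, list(ped_row("proband",
                               if (is.null(blocks$father)) "0" else "father",
                               "mother", 1L, 2L, "proband")))
  if (!is.null(blocks$daughter))
    ped <- c(ped, list(ped_row("daughter", "father", "mother", 2L,
                               if (config$daughter_status == "carrier") 1L else 1L,
                               "daughter")))
  ped <- c(ped, list(ped_row("cfDNA", "0", "mother",
                             if (config$fetal_sex == "male") 1L else 2L,
                             0L, "cfDNA")))
  pedigree <- do.call(rbind, ped)
  rownames(pedigree) <- NULL

  truth <- list(maternal_hap1 = hap1, maternal_hap2 = hap2,
                paternal_hapX = patX, fetal_maternal_hap = fet_mx,
                maternal_auto = rbind(m_a1, m_a2),
                paternal_auto = rbind(p_a1, p_a2),
                fetal_sex = config$fetal_sex,
                fetal_inherits = config$fetal_inherits,
                true_class = true_class,
                recombination_pos = config$recombination_pos,
                variant_interval = vi,
                daughter_status = if (shape == "no_proband_daughter")
                  config$daughter_status else NA_character_)

  structure(list(truth = truth, counts = counts, pedigree = pedigree,
                 panel = panel, config = config),
            class = "family_sim")
}
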