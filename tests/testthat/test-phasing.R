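mini_panel <- function(n = 3)
  data.frame(snp_id = paste0("d", seq_len(n)), chrom = "chrX",
             pos = 31e6 + seq_len(n) * 1000, ref = "A", alt = "G",
             maf = 0.3, region_class = "dmd_flank",
             stringsAsFactors = FALSE)

test_that("a hemizygous proband anchors Hap1 directly", {
  pan <- mini_panel(2)
  mom <- gt_table(pan$snp_id, c(0.5, 0.5))
  pro <- gt_table(pan$snp_id, c(1, 0))   # G at d1, A at d2
  ph <- phase_maternal(mom, pro, "proband", panel = pan)
  expect_equal(ph$hap1_allele, c("G", "A"))
  expect_equal(ph$hap2_allele, c("A", "G"))
  expect_false(attr(ph, "swap_applied"))
  expect_equal(attr(ph, "phasing_source"), "proband")
})

test_that("daughter phasing agrees with Mendelian brute force at every genotype combination", {
  pan <- mini_panel(1)
  mom <- gt_table("d1", 0.5)
  for (p in c(0, 1)) for (d in c(0, 0.5, 1)) {
    # brute force: transmitted maternal allele m must satisfy (m + p)/2 == d
    m_ok <- c(0, 1)[(c(0, 1) + p) / 2 == d]
    for (status in c("carrier", "unaffected")) {
      call_phase <- function() phase_maternal(
        mom, gt_table("d1", d), "daughter",
        paternal_genotypes = gt_table("d1", p),
        daughter_status = status, panel = pan)
      if (length(m_ok) == 0) {
        ph <- suppressWarnings(call_phase())  # Mendelian-inconsistent: dropped
        expect_equal(nrow(ph), 0)
      } else {
        ph <- call_phase()
        hap1_dose_expected <- if (status == "carrier") m_ok else 1 - m_ok
        expect_equal(ph$hap1_dose, hap1_dose_expected)
        expect_equal(attr(ph, "swap_applied"), status == "unaffected")
      }
    }
  }
})

test_that("the published daughter example phases to Hap1 = G", {
  # mother A/G, unaffected daughter A/A, father A: transmitted A -> Hap2
  pan <- mini_panel(1)
  ph <- phase_maternal(gt_table("d1", 0.5), gt_table("d1", 0), "daughter",
                       paternal_genotypes = gt_table("d1", 0),
                       daughter_status = "unaffected", panel = pan)
  expect_equal(ph$hap1_allele, "G")
  expect_true(attr(ph, "swap_applied"))
})

test_that("proband and unaffected-daughter phasing give identical haplotypes", {
  pan <- small_panel(n_dmd = 200, n_chrx = 0, n_chry = 2, n_auto = 5)
  sim <- simulate_family(pan, family_config(seed = 61))
  mom <- hard_genotypes(sim$counts, "mother")
  pro <- hard_genotypes(sim$counts, "proband")
  via_proband <- phase_maternal(mom, pro, "proband", panel = pan)
  # construct the unaffected daughter's genotypes from simulator truth
  tr <- sim$truth
  ids <- names(tr$maternal_hap2)
  daught <- gt_table(ids, (tr$maternal_hap2 + tr$paternal_hapX) / 2)
  dad <- gt_table(ids, tr$paternal_hapX)
  via_daughter <- phase_maternal(mom, daught, "daughter",
                                 paternal_genotypes = dad,
                                 daughter_status = "unaffected", panel = pan)
  shared <- intersect(via_proband$snp_id, via_daughter$snp_id)
  expect_gt(length(shared), 50)
  expect_equal(via_proband$hap1_dose[match(shared, via_proband$snp_id)],
               via_daughter$hap1_dose[match(shared, via_daughter$snp_id)])
})

test_that("phased Hap1 reproduces the simulated maternal Hap1 exactly", {
  pan <- small_panel(n_dmd = 300, n_chrx = 0, n_chry = 2, n_auto = 5)
  sim <- simulate_family(pan, family_config(seed = 71))
  ph <- phase_maternal(hard_genotypes(sim$counts, "mother"),
                       hard_genotypes(sim$counts, "proband"),
                       "proband", panel = pan)
  truth_hap1 <- sim$truth$maternal_hap1[ph$snp_id]
  expect_equal(ph$hap1_dose, unname(truth_hap1))
})

test_that("informative classification follows fetal sex and paternal identity", {
  pan <- mini_panel(2)
  mom <- gt_table(pan$snp_id, c(0.5, 0.5))
  pro <- gt_table(pan$snp_id, c(1, 0))
  ph <- phase_maternal(mom, pro, "proband", panel = pan)

  male <- classify_informative(ph, fetal_sex = "male")
  expect_equal(attr(male, "n_type1"), 2)
  expect_equal(attr(male, "n_type2"), 2)
  expect_equal(male$tracked_allele[male$type_class == "type1"], c("G", "A"))

  # female fetus: d1 Hap1 = G, father A -> Type2-only; with father G -> Type1
  fem <- classify_informative(ph, gt_table(pan$snp_id, c(0, 0)), "female")
  expect_equal(fem$type_class[fem$snp_id == "d1"], "type2")
  fem2 <- classify_informative(ph, gt_table(pan$snp_id, c(1, 1)), "female")
  expect_equal(fem2$type_class[fem2$snp_id == "d1"], "type1")
  expect_true(attr(classify_informative(ph, NULL, "female"),
                   "no_father_fallback"))
})

test_that("male fetuses always have equal Type 1 and Type 2 counts", {
  pan <- small_panel(n_dmd = 150, n_chrx = 0, n_chry = 2, n_auto = 5)
  for (seed in 81:85) {
    sim <- simulate_family(pan, family_config(fetal_sex = "male", seed = seed))
    ph <- phase_maternal(hard_genotypes(sim$counts, "mother"),
                         hard_genotypes(sim$counts, "proband"),
                         "proband", panel = pan)
    inf <- classify_informative(ph, fetal_sex = "male")
    expect_equal(attr(inf, "n_type1"), attr(inf, "n_type2"))
  }
  # and in the clinical cohort table
  tab <- dmd_families()
  male <- tolower(tab$sex) == "male"
  expect_equal(tab$n_type1[male], tab$n_type2[male])
})

test_that("the informative-SNP QC gate fires below 10 of either type", {
  pan <- mini_panel(12)
  mom <- gt_table(pan$snp_id, rep(0.5, 12))
  pro <- gt_table(pan$snp_id, rep(c(0, 1), 6))
  ph <- phase_maternal(mom, pro, "proband", panel = pan)
  ok <- informative_qc(classify_informative(ph, fetal_sex = "male"))
  expect_true(ok$qc_pass)   # 12 of each type: boundary passed
  fem <- classify_informative(ph, gt_table(pan$snp_id, pro$dose), "female")
  bad <- informative_qc(fem)  # all SNPs fall on one type
  expect_false(bad$qc_pass)
  expect_match(bad$decision, "invasive")
})

test_that("unphaseable and degenerate pedigrees raise errors", {
  pan <- mini_panel(2)
  mom_hom <- gt_table(pan$snp_id, c(0, 1))
  expect_error(phase_maternal(mom_hom, gt_table(pan$snp_id, c(0, 1)),
                              "proband", panel = pan), "heterozygous at no")
  mom <- gt_table(pan$snp_id, c(0.5, 0.5))
  expect_error(phase_maternal(mom, gt_table(pan$snp_id, c(0, 0)), "daughter",
                              panel = pan), "requires paternal")
})
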