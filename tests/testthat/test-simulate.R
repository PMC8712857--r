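test_that("cfDNA allele frequency matches the closed-form mixture", {
  # male fetus inheriting Hap1 at f = 0.1: at a maternal-het SNP whose
  # fetal-inherited allele is the Hap1 allele, E[AF] = 0.5(1-f) + f = 0.55
  pan <- small_panel(n_dmd = 800, n_chrx = 0, n_chry = 5, n_auto = 20)
  sim <- simulate_family(pan, family_config(
    fetal_sex = "male", fetal_inherits = "hap1", fetal_fraction = 0.1,
    cfdna_depth = 300, seed = 21))
  tr <- sim$truth
  het <- tr$maternal_hap1 != tr$maternal_hap2
  cf <- sim$counts[sim$counts$sample_id == "cfDNA", ]
  cf <- cf[match(names(tr$maternal_hap1)[het], cf$snp_id), ]
  dep <- cf$ref_count + cf$alt_count
  hap1_af <- ifelse(tr$maternal_hap1[het] == 1, cf$alt_count, cf$ref_count) / dep
  se <- sd(hap1_af) / sqrt(length(hap1_af))
  expect_lt(abs(mean(hap1_af) - 0.55), 3 * se)
})

test_that("f = 0 leaves cfDNA frequencies at the maternal genotype", {
  pan <- small_panel(n_dmd = 600, n_chrx = 0, n_chry = 5, n_auto = 20)
  sim <- simulate_family(pan, family_config(fetal_fraction = 0, seed = 5))
  tr <- sim$truth
  het <- tr$maternal_hap1 != tr$maternal_hap2
  cf <- sim$counts[sim$counts$sample_id == "cfDNA", ]
  cf <- cf[match(names(tr$maternal_hap1)[het], cf$snp_id), ]
  af <- cf$alt_count / (cf$ref_count + cf$alt_count)
  se <- sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - 0.5), 3 * se)
})

test_that("crossover switches the transmitted haplotype at the first SNP past P", {
  pan <- small_panel(n_dmd = 200)
  xpos <- sort(pan$pos[pan$region_class %in% c("dmd_flank", "chrX_common")])
  P <- xpos[100]
  sim <- simulate_family(pan, family_config(
    fetal_inherits = "hap1", recombination_pos = P, seed = 9))
  tr <- sim$truth
  xp <- pan[pan$region_class %in% c("dmd_flank", "chrX_common"), ]
  xp <- xp[order(xp$pos), ]
  before <- xp$pos <= P
  expect_identical(tr$fetal_maternal_hap[before],
                   tr$maternal_hap1[names(tr$fetal_maternal_hap)[before]])
  expect_identical(tr$fetal_maternal_hap[!before],
                   tr$maternal_hap2[names(tr$fetal_maternal_hap)[!before]])
  expect_error(simulate_family(pan, family_config(recombination_pos = 1)),
               "outside")
})

test_that("identical seeds give bit-identical simulations", {
  pan <- small_panel()
  s1 <- simulate_family(pan, family_config(seed = 33))
  s2 <- simulate_family(pan, family_config(seed = 33))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
})

test_that("sample mean depths track the configured depths", {
  pan <- small_panel(n_dmd = 400)
  sim <- simulate_family(pan, family_config(cfdna_depth = 290,
                                            gdna_depth = 150, seed = 2))
  auto <- pan$snp_id[pan$region_class == "autosomal"]
  for (sid in c("mother", "cfDNA")) {
    ct <- sim$counts[sim$counts$sample_id == sid & sim$counts$snp_id %in% auto, ]
    dep <- ct$ref_count + ct$alt_count
    mu <- if (sid == "cfDNA") 290 else 150
    expect_lt(abs(mean(dep) - mu), 3 * sqrt(mu / length(dep)))
  }
})

test_that("pedigrees with >= 300 gene-region SNPs almost always yield >= 10 informative alleles of each type", {
  pan <- small_panel(n_dmd = 300, n_chrx = 0, n_chry = 5, n_auto = 20)
  set.seed(77)
  ok <- vapply(1:100, function(i) {
    sim <- simulate_family(pan, family_config(seed = 1000 + i))
    mom <- hard_genotypes(sim$counts, "mother")
    pro <- hard_genotypes(sim$counts, "proband")
    ph <- phase_maternal(mom, pro, "proband", panel = pan)
    inf <- classify_informative(ph, fetal_sex = "male")
    attr(inf, "n_type1") >= 10 && attr(inf, "n_type2") >= 10
  }, logical(1))
  expect_gte(mean(ok), 0.99)
})

test_that("fixture directories round-trip losslessly", {
  pan <- small_panel(n_dmd = 40, n_chrx = 5, n_chry = 5, n_auto = 10)
  sim <- simulate_family(pan, family_config(
    pedigree_shape = "no_proband_daughter", daughter_status = "carrier",
    recombination_pos = 32e6, seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(sim, dir)
  back <- read_fixture(dir)
  expect_equal(back$panel, sim$panel)
  expect_equal(back$counts, sim$counts)
  expect_equal(back$pedigree, sim$pedigree)
  expect_equal(back$truth$true_class, sim$truth$true_class)
  expect_equal(back$truth$recombination_pos, 32e6)
  expect_equal(back$truth$variant_interval, sim$config$variant_interval)
})

test_that("an empty count table writes a valid header-only file", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "counts.tsv")
  empty <- data.frame(sample_id = character(), snp_id = character(),
                      ref_count = integer(), alt_count = integer(),
                      base_quality_ok = logical())
  write_counts(empty, path)
  back <- read_counts(path)
  expect_equal(nrow(back), 0)
  expect_true(all(c("sample_id", "snp_id", "ref_count", "alt_count") %in%
                    names(back)))
})

test_that("a 21-family batch writes 21 self-contained case directories", {
  pan <- small_panel(n_dmd = 30, n_chrx = 2, n_chry = 2, n_auto = 5)
  root <- withr::local_tempdir()
  for (i in 1:21) {
    sim <- simulate_family(pan, family_config(
      fetal_sex = if (i %% 2) "male" else "female", seed = i))
    write_fixture(sim, file.path(root, sprintf("P%d", i)))
  }
  dirs <- list.dirs(root, recursive = FALSE)
  expect_length(dirs, 21)
  for (d in dirs)
    expect_setequal(list.files(d),
                    c("panel.tsv", "counts.tsv", "pedigree.ped", "truth.txt"))
})
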