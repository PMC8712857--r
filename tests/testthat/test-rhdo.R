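test_that("per-SNP dosage change is the cfDNA-minus-gDNA tracked-allele frequency", {
  pan <- data.frame(snp_id = "d1", chrom = "chrX", pos = 31e6, ref = "A",
                    alt = "G", maf = 0.3, region_class = "dmd_flank")
  inf <- structure(
    data.frame(snp_id = rep("d1", 2), pos = 31e6,
               type_class = c("type1", "type2"),
               tracked_dose = c(1, 0), tracked_allele = c("G", "A"),
               stringsAsFactors = FALSE),
    n_type1 = 1L, n_type2 = 1L, qc_pass = TRUE, no_father_fallback = FALSE,
    class = c("informative_set", "data.frame"))
  cf <- data.frame(sample_id = "cfDNA", snp_id = "d1",
                   ref_count = 45L, alt_count = 55L)
  gd <- data.frame(sample_id = "mother", snp_id = "d1",
                   ref_count = 50L, alt_count = 50L)
  thr <- nipd_thresholds(); thr$min_informative <- 1
  series <- compute_dc(cf, gd, inf, pan, thr)
  expect_equal(series$dc[series$type_class == "type1"], 0.05)
  expect_equal(series$dc[series$type_class == "type2"], -0.05)
})

test_that("mean dosage change converges to +/- f/2 on simulated data", {
  pan <- small_panel(n_dmd = 400, n_chrx = 0, n_chry = 5, n_auto = 20)
  run <- function(f, seed) {
    sim <- simulate_family(pan, family_config(
      fetal_sex = "male", fetal_inherits = "hap1", fetal_fraction = f,
      cfdna_depth = 10000, seed = seed))
    ph <- phase_maternal(hard_genotypes(sim$counts, "mother"),
                         hard_genotypes(sim$counts, "proband"),
                         "proband", panel = pan)
    inf <- classify_informative(ph, fetal_sex = "male")
    compute_dc(sim$counts[sim$counts$sample_id == "cfDNA", ],
               sim$counts[sim$counts$sample_id == "mother", ], inf, pan)
  }
  s <- run(0.10, 91)
  t1 <- s$type_class == "type1"
  se1 <- sd(s$dc[t1]) / sqrt(sum(t1))
  expect_lt(abs(mean(s$dc[t1]) - 0.05), 3 * se1)
  expect_lt(abs(mean(s$dc[!t1]) + 0.05), 3 * se1)
  s0 <- run(0, 92)
  expect_lt(abs(mean(s0$dc[s0$type_class == "type1"])), 3 * se1)
})

test_that("low-depth SNPs are dropped and severe loss raises a QC error", {
  pan <- data.frame(snp_id = paste0("d", 1:30), chrom = "chrX",
                    pos = 31e6 + (1:30) * 1000, ref = "A", alt = "G",
                    maf = 0.3, region_class = "dmd_flank")
  inf <- structure(
    data.frame(snp_id = pan$snp_id, pos = pan$pos,
               type_class = rep(c("type1", "type2"), 15),
               tracked_dose = 1, tracked_allele = "G",
               stringsAsFactors = FALSE),
    n_type1 = 15L, n_type2 = 15L, qc_pass = TRUE, no_father_fallback = FALSE,
    class = c("informative_set", "data.frame"))
  cf <- data.frame(sample_id = "cfDNA", snp_id = pan$snp_id,
                   ref_count = 50L, alt_count = 50L)
  cf$ref_count[1:4] <- 10L; cf$alt_count[1:4] <- 10L  # depth 20 < 70
  gd <- data.frame(sample_id = "mother", snp_id = pan$snp_id,
                   ref_count = 100L, alt_count = 100L)
  series <- compute_dc(cf, gd, inf, pan)
  expect_equal(attr(series, "n_dropped"), 4L)
  expect_equal(nrow(series), 26L)
  cf$ref_count[1:24] <- 10L; cf$alt_count[1:24] <- 10L
  expect_error(compute_dc(cf, gd, inf, pan), "fewer than 10")
})

test_that("Bayes factor matches brute-force binomial enumeration on small instances", {
  set.seed(17)
  for (rep in 1:20) {
    n_snp <- sample(4:12, 1)
    depth <- sample(8:20, n_snp, replace = TRUE)
    k <- rbinom(n_snp, depth, 0.5)
    type <- sample(rep(c("type1", "type2"), length.out = n_snp))
    f <- runif(1, 0.02, 0.12)
    s <- make_series(pos = seq_len(n_snp) * 100L, type_class = type,
                     tracked_count = k, depth = depth)
    res <- bayes_factor(s, f)
    # independent oracle: literal product of binomial pmfs, no log space
    p1 <- ifelse(type == "type1", 0.5 + f / 2, 0.5 - f / 2)
    bf_oracle <- prod(choose(depth, k) * p1^k * (1 - p1)^(depth - k)) /
      prod(choose(depth, k) * (1 - p1)^k * p1^(depth - k))
    expect_lt(abs(res$bf - bf_oracle) / bf_oracle, 1e-9)
  }
})

test_that("relabelling Type 1 <-> Type 2 inverts the Bayes factor", {
  set.seed(23)
  depth <- rep(300L, 40)
  k <- rbinom(40, depth, 0.52)
  type <- rep(c("type1", "type2"), 20)
  s <- make_series(seq_len(40) * 100L, type, k, depth)
  s_swapped <- s
  s_swapped$type_class <- ifelse(type == "type1", "type2", "type1")
  b1 <- bayes_factor(s, 0.05)
  b2 <- bayes_factor(s_swapped, 0.05)
  expect_lt(abs(b1$log10_bf + b2$log10_bf),
            1e-6 * max(abs(b1$log10_bf), 1))
  # and in the segment-normal mode
  n1 <- bayes_factor(s, 0.05, mode = "normal_dc")
  n2 <- bayes_factor(s_swapped, 0.05, mode = "normal_dc")
  expect_lt(abs(n1$log10_bf + n2$log10_bf),
            1e-6 * max(abs(n1$log10_bf), 1))
})

test_that("perfectly balanced data give BF = 1 and a no-call", {
  s <- make_series(seq_len(20) * 100L, rep(c("type1", "type2"), 10),
                   tracked_count = rep(100L, 20), depth = rep(200L, 20))
  res <- bayes_factor(s, 0.05)
  expect_equal(res$bf, 1)
  expect_equal(res$call, "no_call")
  expect_error(bayes_factor(s, 0.005), "redraw")
})

test_that("CBS returns a single segment on a constant-mean series", {
  set.seed(31)
  s <- noisy_series(rep(0.03, 300))
  segs <- segment_cbs(s, f = 0.06)
  expect_equal(nrow(segs), 1)
  expect_length(attr(segs, "switch_positions"), 0)
  short <- noisy_series(rep(0.03, 10))
  expect_warning(seg1 <- segment_cbs(short, f = 0.06), "too short")
  expect_equal(nrow(seg1), 1)
})

test_that("CBS rarely splits a null series and finds an implanted switch", {
  set.seed(37)
  false_split <- vapply(1:50, function(i) {
    nrow(segment_cbs(noisy_series(rep(0.04, 250)), f = 0.08)) > 1
  }, logical(1))
  expect_lte(mean(false_split), 0.05)

  hits <- vapply(1:20, function(i) {
    s <- noisy_series(c(rep(0.04, 150), rep(-0.04, 150)))
    segs <- segment_cbs(s, f = 0.08)
    sw <- attr(segs, "switch_positions")
    length(sw) >= 1 && any(abs(sw / 1000 - 151) <= 10)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("segments partition the series and flag the variant segment once", {
  set.seed(41)
  s <- noisy_series(c(rep(0.04, 120), rep(-0.04, 120)))
  segs <- segment_cbs(s, f = 0.08, variant_interval = c(10000, 20000))
  expect_equal(sum(segs$n_snps), 240)
  expect_equal(sum(segs$contains_variant), 1)
  expect_true(segs$contains_variant[1])
  expect_equal(segs$start_pos[1], 1000)
  expect_equal(segs$end_pos[nrow(segs)], 240000)
})

test_that("genotype classification combines inheritance and sex", {
  mk <- function(bf, call) structure(list(bf = bf, log10_bf = log10(bf),
                                          call = call), class = "bayes_result")
  expect_equal(classify_genotype(mk(2.7e47, "inherits_hap1"), "male")$genotype,
               "affected_male")
  expect_equal(classify_genotype(mk(1.8e80, "inherits_hap1"), "female")$genotype,
               "carrier_female")
  expect_equal(classify_genotype(mk(5.1e-29, "inherits_hap2"), "female")$genotype,
               "normal")
  expect_equal(classify_genotype(mk(5e9, "inherits_hap2"), "male")$genotype,
               "normal")
  nc <- classify_genotype(mk(2, "no_call"), "female", caveats = "x")
  expect_equal(nc$genotype, "no_call")
  expect_equal(nc$caveats, "x")
})
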