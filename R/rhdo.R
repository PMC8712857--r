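#' Per-SNP dosage-change series
#'
#' For every informative allele, computes the tracked-allele frequency in
#' maternal plasma cfDNA and in maternal gDNA and their difference, the
#' per-SNP dosage change `dc = af_cfdna - af_gdna`.  If the fetus inherited
#' Hap1, Type 1 alleles are over-represented in plasma (expected dc +f/2
#' under the homozygous-equivalent model) and Type 2 alleles
#' under-represented; inheritance of Hap2 reverses the signs.  SNPs with
#' cfDNA depth below 70x are dropped (count recorded in the `n_dropped`
#' attribute).
#'
#' @param cfdna_counts,maternal_counts count tables for the plasma and the
#'   maternal gDNA sample.
#' @param informative an [classify_informative()] result.
#' @param panel the SNP panel.
#' @param thresholds see [nipd_thresholds()].
#' @return A `data.frame` of class `"dosage_series"` ordered by position:
#'   `snp_id`, `pos`, `type_class`, `af_cfdna`, `af_gdna`, `dc`,
#'   `tracked_count`, `depth_cfdna`.
#' @export
compute_dc <- function(cfdna_counts, maternal_counts, informative, panel,
                       thresholds = nipd_thresholds()) {
  stopifnot(inherits(informative, "informative_set"))
  cf <- cfdna_counts[match(informative$snp_id, cfdna_counts$snp_id), ]
  gd <- maternal_counts[match(informative$snp_id, maternal_counts$snp_id), ]
  if (anyNA(cf$ref_count) || anyNA(gd$ref_count))
    stop("counts missing at informative SNPs")

  tracked_af <- function(ct, dose) {
    depth <- ct$ref_count + ct$alt_count
    k <- ifelse(dose == 1, ct$alt_count, ct$ref_count)
    list(af = ifelse(depth > 0, k / depth, NA_real_), k = k, depth = depth)
  }
  a_cf <- tracked_af(cf, informative$tracked_dose)
  a_gd <- tracked_af(gd, informative$tracked_dose)

  out <- data.frame(
    snp_id = informative$snp_id, pos = informative$pos,
    type_class = informative$type_class,
    af_cfdna = a_cf$af, af_gdna = a_gd$af,
    dc = a_cf$af - a_gd$af,
    tracked_count = a_cf$k, depth_cfdna = a_cf$depth,
    stringsAsFactors = FALSE)
  keep <- out$depth_cfdna >= thresholds$cfdna_min_depth & !is.na(out$dc)
  n_dropped <- sum(!keep)
  out <- out[keep, ]
  out <- out[order(out$pos, out$type_class), ]
  rownames(out) <- NULL
  n1 <- sum(out$type_class == "type1")
  n2 <- sum(out$type_class == "type2")
  if (n1 < thresholds$min_informative || n2 < thresholds$min_informative)
    stop("fewer than ", thresholds$min_informative,
         " informative SNPs of a type survive depth filtering")
  structure(out, n_dropped = n_dropped,
            class = c("dosage_series", "data.frame"))
}

# oriented per-SNP signal: dc at Type 1 SNPs, -dc at Type 2 SNPs; one value
# per unique SNP (male-fetus series carry both orientations of the same
# counts, which are redundant at the signal level)
oriented_signal <- function(series) {
  s <- ifelse(series$type_class == "type1", series$dc, -series$dc)
  ord <- order(series$pos, series$type_class)
  first <- !duplicated(series$snp_id[ord])
  idx <- ord[first]
  list(s = s[idx], pos = series$pos[idx], idx = idx)
}

#' Segment the dosage series by circular binary segmentation
#'
#' Runs CBS on the oriented per-SNP signal (dc at Type 1 SNPs, -dc at
#' Type 2 SNPs): recursively finds the arc maximizing the standardized
#' mean-difference statistic, accepts splits whose permutation p-value falls
#' below `alpha`, and finally rejoins adjacent segments whose mean
#' difference is below a merge floor (f/4 when the fetal fraction is
#' supplied).  A change in the segment mean along the chromosome is the
#' signature of a meiotic crossover: the fetus switches source haplotype at
#' the boundary.
#'
#' @param series a [compute_dc()] result.
#' @param f fetal fraction, used for the default merge floor; optional.
#' @param variant_interval optional `(start, end)` of the pathogenic lesion;
#'   when given, the segment containing it is flagged `contains_variant`.
#' @param alpha permutation significance level per split (default 0.01).
#' @param n_perm permutations per scan (default 1000).
#' @param min_seg minimum SNPs per segment (default 10).
#' @param merge_floor absolute mean-difference below which adjacent segments
#'   are rejoined; defaults to `f / 4`, or 0 when `f` is missing.
#' @return A `data.frame` of class `"cbs_segments"`: `start_pos`,
#'   `end_pos`, `n_snps`, `mean_dc_type1`, `mean_dc_type2`, `dc`,
#'   `contains_variant`, with attribute `switch_positions` (base positions
#'   of accepted boundaries).
#' @export
segment_cbs <- function(series, f = NULL, variant_interval = NULL,
                        alpha = 0.01, n_perm = 1000, min_seg = 10,
                        merge_floor = NULL) {
  stopifnot(inherits(series, "dosage_series"))
  sig <- oriented_signal(series)
  n <- length(sig$s)
  if (is.null(merge_floor)) merge_floor <- if (is.null(f)) 0 else f / 4

  if (n < 20) {
    warning("dosage series too short for segmentation; returning one segment")
    breaks <- integer(0)
  } else {
    breaks <- cbs_recurse(sig$s, 1L, n, alpha, n_perm, min_seg)
    breaks <- merge_segments(sig$s, breaks, merge_floor)
  }

  bounds <- c(0L, sort(breaks), n)  # break b: cut after signal index b
  segs <- lapply(seq_len(length(bounds) - 1), function(i) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1]
    p1 <- sig$pos[lo]; p2 <- sig$pos[hi]
    rows <- series[series$pos >= p1 & series$pos <= p2, ]
    data.frame(start_pos = p1, end_pos = p2, n_snps = hi - lo + 1L,
               mean_dc_type1 = mean(rows$dc[rows$type_class == "type1"]),
               mean_dc_type2 = mean(rows$dc[rows$type_class == "type2"]))
  })
  segs <- do.call(rbind, segs)
  segs$dc <- segs$mean_dc_type1 - segs$mean_dc_type2
  segs$contains_variant <- FALSE
  if (!is.null(variant_interval)) {
    mid <- mean(variant_interval)
    hit <- which(segs$start_pos <= mid & segs$end_pos >= mid)
    if (length(hit) == 0)  # variant off the series span: nearest segment
      hit <- which.min(pmin(abs(segs$start_pos - mid), abs(segs$end_pos - mid)))
    segs$contains_variant[hit[1]] <- TRUE
  }
  switch_pos <- if (length(bounds) > 2)
    sig$pos[bounds[-c(1, length(bounds))] + 1L] else numeric(0)
  structure(segs, switch_positions = switch_pos,
            class = c("cbs_segments", "data.frame"))
}

# recursive CBS splitter over signal indices [lo, hi]; returns global break
# indices (cut after each returned index)
cbs_recurse <- function(s, lo, hi, alpha, n_perm, min_seg) {
  len <- hi - lo + 1L
  if (len < 2L * min_seg) return(integer(0))
  sc <- cbs_scan(s[lo:hi], min_seg, n_perm, alpha)
  if (is.na(sc$t) || sc$p >= alpha) return(integer(0))
  cuts <- integer(0)
  if (sc$i > 1L) cuts <- c(cuts, lo + sc$i - 2L)       # cut before the arc
  if (sc$j < len) cuts <- c(cuts, lo + sc$j - 1L)      # cut after the arc
  if (length(cuts) == 0) return(integer(0))
  pieces <- cbind(c(lo, cuts + 1L), c(cuts, hi))
  out <- cuts
  for (r in seq_len(nrow(pieces)))
    out <- c(out, cbs_recurse(s, pieces[r, 1], pieces[r, 2],
                              alpha, n_perm, min_seg))
  sort(unique(out))
}

# rejoin adjacent segments whose mean difference is below the floor,
# smallest difference first
merge_segments <- function(s, breaks, floor) {
  breaks <- sort(breaks)
  repeat {
    if (length(breaks) == 0 || floor <= 0) return(breaks)
    bounds <- c(0L, breaks, length(s))
    means <- vapply(seq_len(length(bounds) - 1), function(i)
      mean(s[(bounds[i] + 1):bounds[i + 1]]), numeric(1))
    diffs <- abs(diff(means))
    if (all(diffs >= floor)) return(breaks)
    breaks <- breaks[-which.min(diffs)]
  }
}

#' Bayes factor for the inherited maternal haplotype
#'
#' Compares H1 (the fetus inherited Hap1; Type 1 tracked-allele frequency
#' shifted to 0.5 + f/2 and Type 2 to 0.5 - f/2) against H2 (the mirror
#' image).  The default likelihood is the product over the informative SNPs
#' of the variant-containing segment of binomial likelihoods of the tracked
#' allele count at the per-SNP cfDNA depth; the `"normal_dc"` mode instead
#' models the segment-level dosage change `DC = mean(dc Type1) -
#' mean(dc Type2)` as Gaussian with mean +/- f/2 and binomial sampling
#' variance.  Computation is in log space; Bayes factors of magnitude
#' 10^(+/-300) are reported through `log10_bf`.
#'
#' Calls: `bf >= 10` favours H1 (`inherits_hap1`), `bf <= 0.1` favours H2
#' (`inherits_hap2`), anything between is a no-call.
#'
#' @param segments a [segment_cbs()] result (only the variant-containing
#'   segment contributes), or `NULL` to use the whole series.
#' @param series the [compute_dc()] series.
#' @param f fetal fraction; must be at least 1%, otherwise a redraw is
#'   required and the function refuses.
#' @param mode `"binomial"` (default) or `"normal_dc"`.
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"bayes_result"`: `bf`, `log10_bf`, `call`,
#'   `n_type1`, `n_type2`, `dc_observed`, `mode`.
#' @export
bayes_factor <- function(series, f, segments = NULL,
                         mode = c("binomial", "normal_dc"),
                         thresholds = nipd_thresholds()) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "dosage_series"))
  if (f < thresholds$ff_min)
    stop("fetal fraction below ", thresholds$ff_min,
         ": recommend maternal blood redraw")

  rows <- series
  if (!is.null(segments)) {
    seg <- segments[segments$contains_variant, ]
    if (nrow(seg) == 1)
      rows <- series[series$pos >= seg$start_pos & series$pos <= seg$end_pos, ]
  }
  t1 <- rows$type_class == "type1"
  n1 <- sum(t1); n2 <- sum(!t1)

  if (mode == "binomial") {
    p_hi <- 0.5 + f / 2; p_lo <- 0.5 - f / 2
    p1 <- ifelse(t1, p_hi, p_lo)  # under H1
    p2 <- ifelse(t1, p_lo, p_hi)  # under H2
    log_bf <- sum(dbinom(rows$tracked_count, rows$depth_cfdna, p1, log = TRUE) -
                  dbinom(rows$tracked_count, rows$depth_cfdna, p2, log = TRUE))
  } else {
    d1 <- mean(rows$depth_cfdna[t1]); d2 <- mean(rows$depth_cfdna[!t1])
    dc <- mean(rows$dc[t1]) - mean(rows$dc[!t1])
    v <- 0.25 / (n1 * d1) + 0.25 / (n2 * d2)
    log_bf <- dnorm(dc, f / 2, sqrt(v), log = TRUE) -
              dnorm(dc, -f / 2, sqrt(v), log = TRUE)
  }
  log10_bf <- log_bf / log(10)
  bf <- exp(log_bf)  # may over/underflow to Inf/0 for extreme evidence
  call <- if (log10_bf >= log10(thresholds$bf_hi)) "inherits_hap1"
          else if (log10_bf <= log10(thresholds$bf_lo)) "inherits_hap2"
          else "no_call"
  structure(list(bf = bf, log10_bf = log10_bf, call = call,
                 n_type1 = n1, n_type2 = n2,
                 dc_observed = mean(rows$dc[t1]) - mean(rows$dc[!t1]),
                 mode = mode, f = f),
            class = "bayes_result")
}

#' Combine sex and inheritance into the fetal genotype class
#'
#' An X-linked recessive lesion on the inherited Hap1 makes a male fetus
#' affected and a female fetus a carrier; inheriting Hap2 means an
#' unaffected fetus of either sex.
#'
#' @param bayes a [bayes_factor()] result.
#' @param sex a [call_fetal_sex()] result or `"male"`/`"female"`.
#' @param caveats character vector of reliability caveats to attach.
#' @return A list of class `"nipd_genotype"`: `genotype`
#'   (`"affected_male"`, `"carrier_female"`, `"normal"` or `"no_call"`),
#'   `inherits`, `sex`, `caveats`.
#' @export
classify_genotype <- function(bayes, sex, caveats = character(0)) {
  sx <- if (inherits(sex, "sex_call")) sex$sex else match.arg(sex, c("male", "female"))
  genotype <- switch(bayes$call,
    inherits_hap1 = if (sx == "male") "affected_male" else "carrier_female",
    inherits_hap2 = "normal",
    no_call = "no_call")
  structure(list(genotype = genotype, inherits = bayes$call, sex = sx,
                 caveats = caveats),
            class = "nipd_genotype")
}
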