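#' Fit the full RHDO model to one family
#'
#' Runs the complete noninvasive prenatal diagnosis workflow on a single
#' family: depth QC of every sample, fetal sex from the chrY depth ratio,
#' fetal fraction from autosomal loci, maternal haplotype phasing through
#' the available relative, Type 1 / Type 2 classification, the per-SNP
#' dosage-change series, CBS recombination screening, and the Bayes-factor
#' genotype call on the variant-containing segment.
#'
#' @param counts long-format count table covering every sample of the
#'   family (see [read_counts()]).
#' @param panel the SNP panel ([build_panel()] or [read_panel()]).
#' @param pedigree pedigree table with a `role` column tagging `mother`,
#'   `father` (optional), `proband` or `daughter`, and `cfDNA`.
#' @param variant_interval `(start, end)` base positions of the family's
#'   pathogenic variant.
#' @param daughter_status when phasing through a daughter: `"unaffected"`
#'   or `"carrier"`.
#' @param fetal_fraction optional known fetal fraction; when `NULL`
#'   (default) it is estimated from the data.
#' @param bf_mode likelihood mode for [bayes_factor()].
#' @param cbs run CBS recombination screening (default `TRUE`); when
#'   `FALSE` the whole series forms one segment.
#' @param thresholds see [nipd_thresholds()].
#' @param ... passed on to [segment_cbs()] (e.g. `alpha`, `n_perm`).
#' @return An object of class `"nipd"`: a list with components `genotype`
#'   (the final call), `bayes`, `sex`, `ff`, `depth_qc`, `phasing`,
#'   `informative`, `informative_qc`, `series`, `segments`,
#'   `recombination_detected`, `switch_positions`, `qc_actions` and
#'   `caveats`.  Supports `print()`, `summary()`, `plot()` and `coef()`.
#' @export
#' @examples
#' pan <- build_panel(panel_config(n_dmd_flank = 120, n_chrx = 20,
#'                                 n_chry = 10, n_autosomal = 60), seed = 1)
#' sim <- simulate_family(pan, family_config(fetal_fraction = 0.1,
#'                                           cfdna_depth = 200, seed = 2))
#' fit <- nipd(sim$counts, pan, sim$pedigree,
#'             variant_interval = sim$config$variant_interval)
#' fit$genotype$genotype
nipd <- function(counts, panel, pedigree, variant_interval,
                 daughter_status = c("unaffected", "carrier"),
                 fetal_fraction = NULL,
                 bf_mode = c("binomial", "normal_dc"),
                 cbs = TRUE, thresholds = nipd_thresholds(), ...) {
  bf_mode <- match.arg(bf_mode)
  daughter_status <- match.arg(daughter_status)
  validate_panel(panel)

  role_id <- function(role) {
    id <- pedigree$sample_id[pedigree$role == role]
    if (length(id) == 0) NULL else id[1]
  }
  mother_id <- role_id("mother")
  cf_id <- role_id("cfDNA")
  if (is.null(mother_id) || is.null(cf_id))
    stop("pedigree must tag a mother and a cfDNA sample")
  father_id <- role_id("father")
  proband_id <- role_id("proband")
  daughter_id <- role_id("daughter")

  sample_counts <- function(id) counts[counts$sample_id == id, ]
  caveats <- character(0)

  # --- sample-level QC -----------------------------------------------------
  gdna_ids <- c(mother = mother_id, father = father_id,
                proband = proband_id, daughter = daughter_id)
  dqc <- lapply(gdna_ids, function(id)
    depth_qc(sample_counts(id), "gdna", panel = panel,
             thresholds = thresholds))
  dqc$cfDNA <- depth_qc(sample_counts(cf_id), "cfdna", panel = panel,
                        thresholds = thresholds)
  qc_actions <- vapply(dqc, `[[`, character(1), "action")

  # --- genotypes, sex, fetal fraction -------------------------------------
  cf_counts <- sample_counts(cf_id)
  mother_gt <- hard_genotypes(sample_counts(mother_id),
                              min_depth = thresholds$gdna_min_depth)
  father_gt <- if (!is.null(father_id))
    hard_genotypes(sample_counts(father_id),
                   min_depth = thresholds$gdna_min_depth) else NULL

  sex <- call_fetal_sex(cf_counts, panel, thresholds)

  ff <- estimate_fetal_fraction(cf_counts, mother_gt, father_gt, panel,
                                thresholds = thresholds)
  f <- if (is.null(fetal_fraction)) ff$f else fetal_fraction

  # --- phasing -------------------------------------------------------------
  if (!is.null(proband_id)) {
    phasing <- phase_maternal(mother_gt,
                              hard_genotypes(sample_counts(proband_id),
                                             min_depth = thresholds$gdna_min_depth),
                              "proband", panel = panel)
  } else if (!is.null(daughter_id)) {
    phasing <- phase_maternal(mother_gt,
                              hard_genotypes(sample_counts(daughter_id),
                                             min_depth = thresholds$gdna_min_depth),
                              "daughter", paternal_genotypes = father_gt,
                              daughter_status = daughter_status,
                              panel = panel)
  } else {
    stop("no phasing relative: pedigree has neither proband nor daughter")
  }

  informative <- classify_informative(phasing, father_gt, sex$sex,
                                      thresholds)
  iqc <- informative_qc(informative, thresholds)
  if (attr(informative, "no_father_fallback"))
    caveats <- c(caveats,
                 "female fetus without paternal sample: Type classification by male-fetus rule; reduced reliability")
  if (!iqc$qc_pass)
    stop("informative-SNP QC failed: ", iqc$decision)
  if (is.null(fetal_fraction) && ff$action == "redraw")
    stop("fetal fraction ", signif(ff$f, 3),
         " below minimum: recommend maternal blood redraw")

  # --- dosage series, segmentation, Bayes factor ---------------------------
  series <- compute_dc(cf_counts, sample_counts(mother_id), informative,
                       panel, thresholds)
  segments <- if (cbs)
    segment_cbs(series, f = f, variant_interval = variant_interval, ...)
  else
    segment_cbs_null(series, variant_interval)
  switch_pos <- attr(segments, "switch_positions")

  bayes <- bayes_factor(series, f, segments, mode = bf_mode,
                        thresholds = thresholds)
  genotype <- classify_genotype(bayes, sex, caveats)

  structure(list(genotype = genotype, bayes = bayes, sex = sex, ff = ff,
                 f_used = f, depth_qc = dqc, phasing = phasing,
                 informative = informative, informative_qc = iqc,
                 series = series, segments = segments,
                 recombination_detected = length(switch_pos) > 0,
                 switch_positions = switch_pos,
                 variant_interval = variant_interval,
                 qc_actions = qc_actions, caveats = caveats,
                 thresholds = thresholds),
            class = "nipd")
}

# single-segment fallback used when CBS is disabled
segment_cbs_null <- function(series, variant_interval) {
  t1 <- series$type_class == "type1"
  segs <- data.frame(start_pos = min(series$pos), end_pos = max(series$pos),
                     n_snps = length(unique(series$snp_id)),
                     mean_dc_type1 = mean(series$dc[t1]),
                     mean_dc_type2 = mean(series$dc[!t1]))
  segs$dc <- segs$mean_dc_type1 - segs$mean_dc_type2
  segs$contains_variant <- TRUE
  structure(segs, switch_positions = numeric(0),
            class = c("cbs_segments", "data.frame"))
}

#' @export
print.nipd <- function(x, ...) {
  g <- x$genotype
  cat("Haplotype-based NIPD (RHDO) call\n")
  cat(sprintf("  fetal sex:        %s (chrY ratio %.4f%%)\n",
              g$sex, 100 * x$sex$chry_ratio))
  cat(sprintf("  fetal fraction:   %.2f%% (%d loci)\n",
              100 * x$ff$f, x$ff$n_informative_loci))
  cat(sprintf("  informative SNPs: %d Type 1 / %d Type 2\n",
              attr(x$informative, "n_type1"), attr(x$informative, "n_type2")))
  cat(sprintf("  Bayes factor:     10^%.1f (%s)\n",
              x$bayes$log10_bf, x$bayes$call))
  cat(sprintf("  recombination:    %s\n",
              if (x$recombination_detected)
                paste0("detected at ",
                       paste(format(x$switch_positions, big.mark = ","),
                             collapse = ", "))
              else "none detected"))
  cat(sprintf("  genotype call:    %s\n", g$genotype))
  for (cv in g$caveats) cat("  caveat: ", cv, "\n", sep = "")
  invisible(x)
}

#' @export
summary.nipd <- function(object, ...) {
  structure(list(fit = object), class = "summary.nipd")
}

#' @export
print.summary.nipd <- function(x, ...) {
  print(x$fit)
  segs <- x$fit$segments
  cat("\nSegments:\n")
  print(data.frame(start = segs$start_pos, end = segs$end_pos,
                   n_snps = segs$n_snps, dc = round(segs$dc, 4),
                   variant = segs$contains_variant))
  cat("\nDepth QC actions:\n")
  print(x$fit$qc_actions)
  invisible(x)
}

#' @export
coef.nipd <- function(object, ...) {
  c(fetal_fraction = object$ff$f,
    chry_ratio = object$sex$chry_ratio,
    log10_bf = object$bayes$log10_bf,
    dc_observed = object$bayes$dc_observed)
}

#' Dosage-change scatter for a fitted NIPD model
#'
#' Plots the per-SNP dosage change against genomic position, Type 1 alleles
#' in red and Type 2 in blue, with dashed lines at the +/- f/2 expectations
#' and solid lines at the CBS segment means of each type.  The variant
#' interval is shaded.
#'
#' @param x an [nipd()] fit.
#' @param ... further arguments to `plot()`.
#' @export
plot.nipd <- function(x, ...) {
  s <- x$series
  t1 <- s$type_class == "type1"
  col <- ifelse(t1, "#c0392b", "#2980b9")
  plot(s$pos / 1e6, s$dc, col = col, pch = 20, cex = 0.5,
       xlab = "chrX position (Mb)", ylab = "dosage change (DC)", ...)
  f <- x$f_used
  abline(h = c(f / 2, -f / 2), lty = 2, col = c("#c0392b", "#2980b9"))
  if (!is.null(x$variant_interval)) {
    usr <- graphics::par("usr")
    graphics::rect(x$variant_interval[1] / 1e6, usr[3],
                   x$variant_interval[2] / 1e6, usr[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  for (i in seq_len(nrow(x$segments))) {
    seg <- x$segments[i, ]
    segments(seg$start_pos / 1e6, seg$mean_dc_type1,
             seg$end_pos / 1e6, seg$mean_dc_type1, col = "#c0392b", lwd = 2)
    segments(seg$start_pos / 1e6, seg$mean_dc_type2,
             seg$end_pos / 1e6, seg$mean_dc_type2, col = "#2980b9", lwd = 2)
  }
  legend("topright", legend = c("Type 1", "Type 2"), col = c("#c0392b", "#2980b9"),
         pch = 20, bty = "n")
  invisible(x)
}
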