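#' Parse a pathogenic-variant label
#'
#' Variant labels follow the exon-range shorthand used in clinical DMD
#' reporting (`EX50del`, `EX8_9dup`, `EX53_55del`) or an HGVS-like coding
#' change (`c.3055C > T`), which is classified as a point variant.
#'
#' @param label a single variant label.
#' @return A list of class `"variant_class"`: `kind` (`"deletion"`,
#'   `"duplication"` or `"point"`), `exon_start`, `exon_end` (`NA` for
#'   point variants).
#' @export
#' @examples
#' classify_variant_label("EX46_51del")$kind
classify_variant_label <- function(label) {
  stopifnot(length(label) == 1, is.character(label))
  m <- regmatches(label, regexec("^EX([0-9]+)(?:_([0-9]+))?(del|dup)$", label))[[1]]
  if (length(m) > 0) {
    e1 <- as.integer(m[2])
    e2 <- if (nzchar(m[3])) as.integer(m[3]) else e1
    if (e1 > e2) stop("exon range reversed in label: ", label)
    return(structure(list(kind = if (m[4] == "del") "deletion" else "duplication",
                          exon_start = e1, exon_end = e2),
                     class = "variant_class"))
  }
  if (grepl("^c\\.", label))
    return(structure(list(kind = "point", exon_start = NA_integer_,
                          exon_end = NA_integer_), class = "variant_class"))
  stop("unparseable variant label: ", label)
}

#' Read a cohort case table
#'
#' Tab-separated table with one row per family: `family_id`,
#' `gestational_age` (weeks+days, e.g. `"10+3"`), `variant_label`,
#' `ff_percent`, `sex`, `n_type1`, `n_type2`, `bf`, `nipd_result`,
#' `invasive_result`.
#'
#' @param path file path.
#' @return A `data.frame` of case records.
#' @export
read_case_table <- function(path) {
  rec <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("family_id", "gestational_age", "variant_label", "ff_percent",
            "sex", "n_type1", "n_type2", "bf", "nipd_result",
            "invasive_result")
  if (!all(need %in% names(rec)))
    stop("case table must have columns ", paste(need, collapse = ", "))
  rec$bf <- as.numeric(rec$bf)
  rec
}

#' The packaged 21-family DMD NIPD cohort
#'
#' A transcription of the published per-family summary of 21 DMD families
#' (P1-P21): gestational age, pathogenic variant, fetal fraction, fetal
#' sex, Type 1 / Type 2 informative-allele counts, Bayes factor, and the
#' NIPD and invasive-diagnosis results.
#'
#' @return A `data.frame` with 21 rows (see [read_case_table()]).
#' @export
#' @examples
#' median(dmd_families()$ff_percent)
dmd_families <- function() {
  read_case_table(system.file("extdata", "dmd_cohort21.tsv",
                              package = "haplodose", mustWork = TRUE))
}

ga_to_days <- function(ga) {
  parts <- strsplit(ga, "+", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 7 + as.numeric(p[2]),
         numeric(1))
}

#' Cohort-level summary statistics
#'
#' Reproduces the standard cohort descriptives from a case table: fetal
#' fraction range and median, mean informative-allele counts
#' (integer-rounded), counts and percentages (1 decimal place) by sex,
#' NIPD result and variant kind, the deletion and duplication hotspot
#' fractions, mean gestational age (averaged in days, truncated to
#' completed days), and NIPD-vs-invasive concordance.
#'
#' The deletion hotspot fraction is the share of deletions whose exon range
#' is fully contained in exons 44-55.  For duplications the membership rule
#' is configurable: `"start"` (default; the start exon lies in 8-12),
#' `"containment"`, or `"overlap"`.
#'
#' @param records a case table ([read_case_table()] / [dmd_families()]).
#' @param dup_hotspot_rule see Details.
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"cohort_summary"`.
#' @export
#' @examples
#' summarize_cohort(dmd_families())$ff_median
summarize_cohort <- function(records,
                             dup_hotspot_rule = c("start", "containment",
                                                  "overlap"),
                             thresholds = nipd_thresholds()) {
  dup_hotspot_rule <- match.arg(dup_hotspot_rule)
  if (nrow(records) == 0) stop("empty case table")
  vc <- lapply(records$variant_label, classify_variant_label)
  kind <- vapply(vc, `[[`, character(1), "kind")
  e1 <- vapply(vc, `[[`, integer(1), "exon_start")
  e2 <- vapply(vc, `[[`, integer(1), "exon_end")

  pct1 <- function(x) round(100 * x, 1)
  dele <- kind == "deletion"
  dupl <- kind == "duplication"
  del_hot <- dele & e1 >= 44 & e2 <= 55
  dup_hot <- dupl & switch(dup_hotspot_rule,
    start = e1 >= 8 & e1 <= 12,
    containment = e1 >= 8 & e2 <= 12,
    overlap = e1 <= 12 & e2 >= 8)

  ga_days <- mean(ga_to_days(records$gestational_age))
  hi <- records$bf >= thresholds$bf_hi

  structure(list(
    n_families = nrow(records),
    ff_min = min(records$ff_percent),
    ff_max = max(records$ff_percent),
    ff_median = median(records$ff_percent),
    mean_type1 = round(mean(records$n_type1)),
    mean_type2 = round(mean(records$n_type2)),
    range_type1 = range(records$n_type1),
    range_type2 = range(records$n_type2),
    n_by_sex = table(records$sex),
    n_by_result = table(records$nipd_result),
    n_by_kind = table(factor(kind, c("deletion", "duplication", "point"))),
    pct_by_kind = pct1(table(factor(kind, c("deletion", "duplication",
                                            "point"))) / length(kind)),
    deletion_hotspot_pct = pct1(sum(del_hot) / max(sum(dele), 1)),
    duplication_hotspot_pct = pct1(sum(dup_hot) / max(sum(dupl), 1)),
    dup_hotspot_rule = dup_hotspot_rule,
    mean_ga = sprintf("%d+%d", floor(ga_days / 7), floor(ga_days %% 7)),
    n_affected_male = sum(hi & tolower(records$sex) == "male"),
    n_carrier_female = sum(hi & tolower(records$sex) == "female"),
    concordance = mean(records$nipd_result == records$invasive_result)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d families\n", x$n_families))
  cat(sprintf("  fetal fraction: median %.2f%% (range %.2f-%.2f%%)\n",
              x$ff_median, x$ff_min, x$ff_max))
  cat(sprintf("  informative alleles: mean Type 1 %d (%d-%d), Type 2 %d (%d-%d)\n",
              x$mean_type1, x$range_type1[1], x$range_type1[2],
              x$mean_type2, x$range_type2[1], x$range_type2[2]))
  k <- x$n_by_kind; p <- x$pct_by_kind
  cat(sprintf("  variants: %d deletions (%.1f%%), %d duplications (%.1f%%), %d point (%.1f%%)\n",
              k[["deletion"]], p[["deletion"]], k[["duplication"]],
              p[["duplication"]], k[["point"]], p[["point"]]))
  cat(sprintf("  hotspots: %.1f%% of deletions in exons 44-55; %.1f%% of duplications in exons 8-12 (%s rule)\n",
              x$deletion_hotspot_pct, x$duplication_hotspot_pct,
              x$dup_hotspot_rule))
  cat(sprintf("  calls: %d affected male, %d carrier female; concordance with invasive diagnosis %.0f%%\n",
              x$n_affected_male, x$n_carrier_female, 100 * x$concordance))
  invisible(x)
}

#' Correlation of Bayes factor with fetal fraction
#'
#' Splits the cohort into fetuses called as inheriting Hap1 (BF >= 10) and
#' Hap2 (BF <= 0.1) and computes, within each group, the Pearson
#' correlation of fetal fraction with log10(BF) and its two-sided t-test
#' p-value.  More fetal DNA gives stronger evidence, so the correlation is
#' expected positive in the Hap1 group and negative in the Hap2 group.
#'
#' @param records a case table; `ff_percent` and `bf` columns are used.
#' @param thresholds see [nipd_thresholds()].
#' @return A list with components `hap1` and `hap2`, each either `NULL`
#'   (fewer than 3 records or degenerate fetal fractions) or a list
#'   `n`, `r`, `p`.
#' @export
#' @examples
#' bf_ff_correlation(dmd_families())$hap1$r
bf_ff_correlation <- function(records, thresholds = nipd_thresholds()) {
  one_group <- function(rows) {
    if (nrow(rows) < 3 || length(unique(rows$ff_percent)) < 2 ||
        length(unique(rows$bf)) < 2) return(NULL)
    ct <- cor.test(rows$ff_percent, log10(rows$bf), method = "pearson")
    list(n = nrow(rows), r = unname(ct$estimate), p = ct$p.value)
  }
  list(hap1 = one_group(records[records$bf >= thresholds$bf_hi, ]),
       hap2 = one_group(records[records$bf <= thresholds$bf_lo, ]))
}

#' Render a per-family clinical report
#'
#' Assembles the NIPD outcome into a human-readable report with the
#' follow-up recommendation used in clinical workflows: chorionic villus
#' sampling to confirm an affected call, amniocentesis for carrier and
#' normal calls, and a repeat blood draw after two weeks for a no-call.
#'
#' @param fit an [nipd()] fit (or a list with compatible fields).
#' @param family_id family identifier for the header.
#' @return A list of class `"nipd_report"`: structured `record` plus
#'   `text` lines.  `print()`ing shows the text; the record serializes
#'   cleanly to JSON.
#' @export
render_report <- function(fit, family_id = "family") {
  if (is.null(fit$genotype)) stop("missing genotype call in fit")
  g <- fit$genotype
  rec <- list(
    family_id = family_id,
    fetal_sex = g$sex,
    fetal_fraction = fit$ff$f,
    log10_bf = fit$bayes$log10_bf,
    bf = fit$bayes$bf,
    genotype = g$genotype,
    recombination_detected = isTRUE(fit$recombination_detected),
    switch_positions = as.numeric(fit$switch_positions),
    qc_actions = as.list(fit$qc_actions),
    caveats = g$caveats,
    recommendation = switch(g$genotype,
      affected_male = "confirm by invasive diagnosis (chorionic villus sampling)",
      carrier_female = "confirm by invasive diagnosis (amniocentesis)",
      normal = "confirm by invasive diagnosis (amniocentesis)",
      no_call = "no call: repeat maternal blood draw in 2 weeks"))
  text <- c(
    sprintf("NIPD report - %s", family_id),
    sprintf("  fetal sex: %s; fetal fraction: %.2f%%", rec$fetal_sex,
            100 * rec$fetal_fraction),
    sprintf("  Bayes factor: 10^%.1f -> %s", rec$log10_bf, rec$genotype),
    if (rec$recombination_detected)
      sprintf("  recombination detected (switch at %s)",
              paste(format(rec$switch_positions, big.mark = ","),
                    collapse = ", ")) else "  no recombination detected",
    paste0("  recommendation: ", rec$recommendation),
    if (length(rec$caveats)) paste0("  caveat: ", rec$caveats) else NULL)
  structure(list(record = rec, text = text), class = "nipd_report")
}

#' @export
print.nipd_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
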