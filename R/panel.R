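#' SNP capture-panel configuration
#'
#' Describes a targeted capture panel for X-linked RHDO: SNPs flanking and
#' spanning the disease gene (used for phasing and dosage), common chrX SNPs,
#' chrY presence/absence sites (fetal sex), and autosomal SNPs (fetal
#' fraction).  Defaults mirror a published DMD NIPD panel: 1,511 gene-region
#' SNPs with minor-allele frequency (MAF) above 0.10 within the gene plus
#' 0.5 Mb of flank, 203 chrX and 213 autosomal SNPs with MAF above 0.45, and
#' 35 chrY sites, on GRCh37 coordinates.
#'
#' @param n_dmd_flank,n_chrx,n_chry,n_autosomal number of SNPs (or chrY
#'   sites) per region class; all must be positive except that `n_chrx`,
#'   `n_chry` and `n_autosomal` may be zero.
#' @param gene_start,gene_end 1-based inclusive bounds of the disease gene on
#'   chrX (GRCh37 DMD locus by default).
#' @param flank flank width in bases added on each side of the gene for the
#'   `dmd_flank` class.
#' @param maf_floor_dmd,maf_floor_common lower MAF bounds for the gene-region
#'   class and for the chrX/autosomal classes.
#' @return A list of class `"panel_config"`.
#' @seealso [build_panel()]
#' @export
panel_config <- function(n_dmd_flank = 1511L, n_chrx = 203L, n_chry = 35L,
                         n_autosomal = 213L,
                         gene_start = 31137345L, gene_end = 33229673L,
                         flank = 5e5,
                         maf_floor_dmd = 0.10, maf_floor_common = 0.45) {
  if (n_dmd_flank <= 0)
    stop("panel must contain at least one gene-region (dmd_flank) SNP")
  if (n_chrx < 0 || n_chry < 0 || n_autosomal < 0)
    stop("panel class sizes must be non-negative")
  if (gene_start >= gene_end || gene_start - flank < 1)
    stop("invalid gene window")
  structure(list(n_dmd_flank = as.integer(n_dmd_flank),
                 n_chrx = as.integer(n_chrx), n_chry = as.integer(n_chry),
                 n_autosomal = as.integer(n_autosomal),
                 gene_start = gene_start, gene_end = gene_end, flank = flank,
                 maf_floor_dmd = maf_floor_dmd,
                 maf_floor_common = maf_floor_common),
            class = "panel_config")
}

#' Build a synthetic SNP capture panel
#'
#' Draws SNP positions and population allele frequencies for each region
#' class of a [panel_config()].  Positions are strictly increasing within a
#' chromosome; `dmd_flank` SNPs fall inside the gene +/- flank window on
#' chrX; MAFs are uniform above the class floor (`dmd_flank` above 0.10,
#' `chrX_common`/`autosomal` above 0.45 by default).  chrY sites carry no
#' alleles (`maf = NA`); they are presence/absence depth markers.
#'
#' @param config a [panel_config()].
#' @param seed integer RNG seed; identical seeds give identical panels.
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `maf`, `region_class`.
#' @export
#' @examples
#' pan <- build_panel(panel_config(n_dmd_flank = 50, n_chrx = 10,
#'                                 n_chry = 5, n_autosomal = 20), seed = 1)
#' table(pan$region_class)
build_panel <- function(config = panel_config(), seed = NULL) {
  stopifnot(inherits(config, "panel_config"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")

  draw_positions <- function(n, lo, hi) {
    stopifnot(hi - lo + 1 >= n)
    sort(sample.int(hi - lo + 1, n)) + lo - 1
  }
  draw_alleles <- function(n) {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    list(ref = ref, alt = unname(alt))
  }

  win_lo <- as.integer(config$gene_start - config$flank)
  win_hi <- as.integer(config$gene_end + config$flank)

  blocks <- list()
  al <- draw_alleles(config$n_dmd_flank)
  blocks$dmd <- data.frame(
    chrom = "chrX",
    pos = draw_positions(config$n_dmd_flank, win_lo, win_hi),
    ref = al$ref, alt = al$alt,
    maf = runif(config$n_dmd_flank, config$maf_floor_dmd, 0.5),
    region_class = "dmd_flank", stringsAsFactors = FALSE)

  if (config$n_chrx > 0) {
    # common chrX SNPs live outside the gene window, short-arm side
    al <- draw_alleles(config$n_chrx)
    blocks$chrx <- data.frame(
      chrom = "chrX",
      pos = draw_positions(config$n_chrx, 1e6, win_lo - 1),
      ref = al$ref, alt = al$alt,
      maf = runif(config$n_chrx, config$maf_floor_common, 0.5),
      region_class = "chrX_common", stringsAsFactors = FALSE)
  }
  if (config$n_chry > 0) {
    blocks$chry <- data.frame(
      chrom = "chrY",
      pos = draw_positions(config$n_chry, 2e6, 28e6),
      ref = "N", alt = "N", maf = NA_real_,
      region_class = "chrY_site", stringsAsFactors = FALSE)
  }
  if (config$n_autosomal > 0) {
    chroms <- sort(sample.int(22, config$n_autosomal, replace = TRUE))
    al <- draw_alleles(config$n_autosomal)
    pos <- unlist(lapply(split(seq_along(chroms), chroms), function(idx)
      draw_positions(length(idx), 1e6, 45e6)), use.names = FALSE)
    blocks$auto <- data.frame(
      chrom = paste0("chr", chroms), pos = pos,
      ref = al$ref, alt = al$alt,
      maf = runif(config$n_autosomal, config$maf_floor_common, 0.5),
      region_class = "autosomal", stringsAsFactors = FALSE)
  }

  panel <- do.call(rbind, blocks)
  ord <- order(match(panel$chrom, c(paste0("chr", 1:22), "chrX", "chrY")),
               panel$pos)
  panel <- panel[ord, , drop = FALSE]
  panel$snp_id <- sprintf("snp%05d", seq_len(nrow(panel)))
  rownames(panel) <- NULL
  panel[, c("snp_id", "chrom", "pos", "ref", "alt", "maf", "region_class")]
}

# internal: check structural invariants of a panel table
validate_panel <- function(panel, config = NULL) {
  stopifnot(is.data.frame(panel),
            all(c("snp_id", "chrom", "pos", "maf", "region_class") %in%
                  names(panel)))
  by_chr <- split(panel$pos, panel$chrom)
  if (!all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
    stop("panel positions must be strictly increasing within a chromosome")
  if (anyDuplicated(panel$snp_id)) stop("duplicated snp_id in panel")
  invisible(panel)
}
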