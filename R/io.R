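#' Read and write the package's tabular interchange files
#'
#' Plain tab-separated formats shared by the simulator and the analysis
#' functions: a panel file (`snp_id`, `chrom`, `pos`, `ref`, `alt`, `maf`,
#' `region_class`), a count file (`sample_id`, `snp_id`, `ref_count`,
#' `alt_count`, optional `base_quality_ok`), a PED-like pedigree file
#' (`family_id`, `sample_id`, `father_id`, `mother_id`, `sex`, `affected`,
#' `role`) and a key=value truth file.
#'
#' @param x table to write.
#' @param path file path.
#' @return Readers return a `data.frame` (or a named list for the truth
#'   file); writers return `path` invisibly.
#' @name nipd_io
NULL

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname nipd_io
#' @export
write_panel <- function(x, path) write_tsv(x, path)

#' @rdname nipd_io
#' @export
read_panel <- function(path) {
  p <- read.delim(path, stringsAsFactors = FALSE)
  p$pos <- as.integer(p$pos)
  validate_panel(p)
}

#' @rdname nipd_io
#' @export
write_counts <- function(x, path) write_tsv(x, path)

#' @rdname nipd_io
#' @export
read_counts <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "snp_id", "ref_count", "alt_count")
  if (!all(need %in% names(ct)))
    stop("count file must have columns ", paste(need, collapse = ", "))
  if (is.null(ct$base_quality_ok)) ct$base_quality_ok <- TRUE
  ct
}

#' @rdname nipd_io
#' @export
write_pedigree <- function(x, path) write_tsv(x, path)

#' @rdname nipd_io
#' @export
read_pedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(father_id = "character",
                                      mother_id = "character"))
  need <- c("family_id", "sample_id", "father_id", "mother_id", "sex",
            "affected", "role")
  if (!all(need %in% names(ped)))
    stop("pedigree file must have columns ", paste(need, collapse = ", "))
  ped
}

write_truth <- function(truth, path) {
  rp <- truth$recombination_pos
  lines <- c(
    paste0("fetal_sex=", truth$fetal_sex),
    paste0("fetal_inherits=", truth$fetal_inherits),
    paste0("true_class=", truth$true_class),
    paste0("recombination_pos=", if (is.null(rp)) "NA" else rp),
    paste0("variant_start=", truth$variant_interval[1]),
    paste0("variant_end=", truth$variant_interval[2]))
  writeLines(lines, path)
  invisible(path)
}

read_truth <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  list(fetal_sex = vals[["fetal_sex"]],
       fetal_inherits = vals[["fetal_inherits"]],
       true_class = vals[["true_class"]],
       recombination_pos = if (vals[["recombination_pos"]] == "NA") NULL
                           else as.numeric(vals[["recombination_pos"]]),
       variant_interval = c(as.numeric(vals[["variant_start"]]),
                            as.numeric(vals[["variant_end"]])))
}

#' Write a simulated family to a self-contained case directory
#'
#' Emits `panel.tsv`, `counts.tsv`, `pedigree.ped` and `truth.txt` into
#' `dir`.  The tabular files round-trip losslessly through [read_fixture()].
#'
#' @param sim a `"family_sim"` object from [simulate_family()].
#' @param dir directory to create/write into.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "family_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  write_panel(sim$panel, file.path(dir, "panel.tsv"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_pedigree(sim$pedigree, file.path(dir, "pedigree.ped"))
  write_truth(sim$truth, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Read a case directory written by [write_fixture()]
#'
#' @param dir case directory.
#' @return A list with `panel`, `counts`, `pedigree` and `truth` (the truth
#'   holds the scalar record only: sex, inheritance, class, crossover,
#'   variant interval).
#' @export
read_fixture <- function(dir) {
  list(panel = read_panel(file.path(dir, "panel.tsv")),
       counts = read_counts(file.path(dir, "counts.tsv")),
       pedigree = read_pedigree(file.path(dir, "pedigree.ped")),
       truth = read_truth(file.path(dir, "truth.txt")))
}
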