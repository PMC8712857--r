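#' Binomial in-silico performance model for the RHDO assay
#'
#' Predicts the sensitivity, specificity and no-call rate of the
#' Bayes-factor call at a given fetal fraction, informative-SNP count and
#' sequencing depth.  Each replicate draws tracked-allele counts at every
#' SNP from a binomial distribution with success probability 0.5 + f/2
#' (Type 1) and 0.5 - f/2 (Type 2) under H1 — and the mirror image under
#' H2 — then forms the same per-SNP binomial Bayes factor as
#' [bayes_factor()].  With a common depth the log Bayes factor depends on
#' the counts only through their per-type totals, which the implementation
#' exploits; the result is numerically identical to the per-SNP product.
#'
#' Sensitivity is the fraction of H1 replicates with BF >= 10 (no-calls
#' count as non-sensitive), specificity the fraction of H2 replicates with
#' BF <= 0.1, and the no-call rate the average fraction of replicates
#' falling in (0.1, 10) under the two hypotheses.  An expected sensitivity
#' below 95% triggers a redraw recommendation.
#'
#' @param f fetal fraction (> 0).
#' @param n_snps total informative SNPs, split evenly between the two types
#'   (must be >= 2).
#' @param depth reads per SNP (>= 1).
#' @param n_reps Monte-Carlo replicates (default 10^4; the full-scale run of
#'   10^6 is available by setting it).
#' @param seed RNG seed; identical seeds give identical estimates.
#' @param thresholds see [nipd_thresholds()].
#' @return A list of class `"performance_estimate"`: `f`, `n_snps`,
#'   `depth`, `n_reps`, `sensitivity`, `specificity`, `no_call_rate`,
#'   `recommend_redraw`.
#' @export
#' @examples
#' predict_performance(f = 0.05, n_snps = 100, depth = 200,
#'                     n_reps = 2000, seed = 1)$sensitivity
predict_performance <- function(f, n_snps, depth, n_reps = 1e4, seed = NULL,
                                thresholds = nipd_thresholds()) {
  if (f <= 0 || n_snps < 2 || depth < 1 || n_reps < 1)
    stop("invalid performance-model parameters")
  if (!is.null(seed)) set.seed(seed)
  n1 <- floor(n_snps / 2); n2 <- n_snps - n1
  p_hi <- 0.5 + f / 2; p_lo <- 0.5 - f / 2
  # per-read log-likelihood contrasts; lnBF is linear in the count totals
  c_hit <- log(p_hi / p_lo)           # tracked read under its favoured type
  c_miss <- log((1 - p_hi) / (1 - p_lo))

  log10_bf <- function(k1, k2, N1, N2) {
    # sum over SNPs of log B(k; n, p_H1) - log B(k; n, p_H2), via totals
    ln <- k1 * c_hit + (N1 - k1) * c_miss -
      (k2 * c_hit + (N2 - k2) * c_miss)
    ln / log(10)
  }
  N1 <- n1 * depth; N2 <- n2 * depth
  hi <- log10(thresholds$bf_hi); lo <- log10(thresholds$bf_lo)

  # H1: Type 1 totals at p_hi, Type 2 at p_lo
  b_h1 <- log10_bf(rbinom(n_reps, N1, p_hi), rbinom(n_reps, N2, p_lo), N1, N2)
  # H2: mirror image
  b_h2 <- log10_bf(rbinom(n_reps, N1, p_lo), rbinom(n_reps, N2, p_hi), N1, N2)

  sens <- mean(b_h1 >= hi)
  spec <- mean(b_h2 <= lo)
  no_call <- (mean(b_h1 > lo & b_h1 < hi) + mean(b_h2 > lo & b_h2 < hi)) / 2
  structure(list(f = f, n_snps = n_snps, depth = depth, n_reps = n_reps,
                 sensitivity = sens, specificity = spec,
                 no_call_rate = no_call,
                 recommend_redraw = sens < 0.95),
            class = "performance_estimate")
}

#' @export
print.performance_estimate <- function(x, ...) {
  cat(sprintf(paste0("In-silico RHDO performance (f = %.2f%%, %d SNPs, ",
                     "%gx, %g reps)\n"),
              100 * x$f, x$n_snps, x$depth, x$n_reps))
  cat(sprintf("  sensitivity %.4f  specificity %.4f  no-call %.4f%s\n",
              x$sensitivity, x$specificity, x$no_call_rate,
              if (x$recommend_redraw) "  [recommend redraw]" else ""))
  invisible(x)
}

#' Performance surface over fetal fraction, SNP count and depth
#'
#' Evaluates [predict_performance()] on the grid
#' `expand.grid(f_grid, snp_grid, depth_grid)`, e.g. to tabulate the 3-D
#' surface of predicted sensitivity/specificity against informative-SNP
#' count and depth at fetal fractions of 1, 2, 4 and 8%.
#'
#' @param f_grid,snp_grid,depth_grid non-empty numeric grids.
#' @param n_reps replicates per grid point.
#' @param seed RNG seed (each point gets a derived sub-seed).
#' @param thresholds see [nipd_thresholds()].
#' @return A `data.frame` with one row per grid point: `f`, `n_snps`,
#'   `depth`, `sensitivity`, `specificity`, `no_call_rate`,
#'   `recommend_redraw`.
#' @export
performance_surface <- function(f_grid, snp_grid, depth_grid, n_reps = 1e4,
                                seed = NULL,
                                thresholds = nipd_thresholds()) {
  if (length(f_grid) == 0 || length(snp_grid) == 0 || length(depth_grid) == 0)
    stop("grids must be non-empty")
  grid <- expand.grid(f = f_grid, n_snps = snp_grid, depth = depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    est <- predict_performance(grid$f[i], grid$n_snps[i], grid$depth[i],
                               n_reps = n_reps, seed = seeds[i],
                               thresholds = thresholds)
    data.frame(f = est$f, n_snps = est$n_snps, depth = est$depth,
               sensitivity = est$sensitivity, specificity = est$specificity,
               no_call_rate = est$no_call_rate,
               recommend_redraw = est$recommend_redraw)
  })
  do.call(rbind, rows)
}
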