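## Summary-statistic arithmetic: z-to-beta conversion, fixed-effect
## meta-analysis, probe-level QC filters and variance explained.

#' Effect size and SE from a z-statistic
#'
#' Recovers a per-allele effect in phenotype SD units from a z-statistic,
#' the effect-allele frequency and the sample size:
#' `se = 1 / sqrt(2 f (1 - f) (n + z^2))`, `beta = z * se`. By
#' construction `beta / se` returns `z` exactly.
#'
#' @param z z-statistic.
#' @param freq effect-allele frequency in (0, 1).
#' @param n sample size (>= 2).
#' @return list with `beta` and `se` (vectorized).
#' @export
beta_from_z <- function(z, freq, n) {
  if (any(freq <= 0 | freq >= 1)) stop("freq must be in (0, 1)")
  if (any(n < 2)) stop("n must be >= 2")
  se <- 1 / sqrt(2 * freq * (1 - freq) * (n + z^2))
  list(beta = z * se, se = se)
}

#' Inverse-variance fixed-effect meta-analysis of two cohorts
#'
#' SNPs must already be harmonized to the same effect alleles. SNPs
#' present in only one cohort are dropped: carrying over single-cohort
#' estimates would mix standard errors of different scales.
#'
#' @param a,b summary tables (internal columns).
#' @return meta-analysed summary table; `freq` is the sample-size
#'   weighted average, `n` the sum.
#' @export
meta_fixed <- function(a, b) {
  shared <- intersect(a$snp, b$snp)
  ia <- match(shared, a$snp)
  ib <- match(shared, b$snp)
  x <- a[ia]
  y <- b[ib]
  if (nrow(x) && !all(x$a1 == y$a1 & x$a2 == y$a2))
    stop("meta_fixed inputs are not harmonized to the same alleles")
  wa <- 1 / x$se^2
  wb <- 1 / y$se^2
  bm <- (x$b * wa + y$b * wb) / (wa + wb)
  sem <- 1 / sqrt(wa + wb)
  logp <- pchisq((bm / sem)^2, df = 1, lower.tail = FALSE, log.p = TRUE)
  data.table::data.table(
    snp = x$snp, chrom = x$chrom, bp = x$bp, a1 = x$a1, a2 = x$a2,
    freq = (x$freq * x$n + y$freq * y$n) / (x$n + y$n),
    b = bm, se = sem, p = exp(logp), logp = logp, n = x$n + y$n)
}

#' QC filter for a collection of cis summaries
#'
#' Applies, in order: (1) per-SNP MAF filter, (2) instrument filter —
#' the probe must retain at least one cis SNP with `p < min_instrument_p`,
#' (3) exclusion of probes inside the MHC region. Default MHC coordinates
#' are chr6:25-34 Mb (GRCh37).
#'
#' @param cis_list named list of `CisSummary` objects.
#' @param min_instrument_p instrument significance threshold
#'   (default 5e-8).
#' @param mhc list with `chrom`, `start`, `end` (1-based inclusive), or
#'   `NULL` to skip.
#' @param min_maf minor-allele-frequency floor (default 0.01).
#' @return filtered list; `attr(x, "report")` counts exclusions per rule
#'   (`snp_maf` counts SNPs, the others probes).
#' @export
filter_probes <- function(cis_list, min_instrument_p = 5e-8,
                          mhc = list(chrom = "6", start = 25e6, end = 34e6),
                          min_maf = 0.01) {
  report <- c(snp_maf = 0L, no_instrument = 0L, mhc = 0L)
  log_thr <- log(min_instrument_p)
  out <- list()
  for (id in names(cis_list)) {
    cs <- cis_list[[id]]
    recs <- cs$records
    maf <- pmin(recs$freq, 1 - recs$freq)
    drop <- maf < min_maf
    report["snp_maf"] <- report["snp_maf"] + sum(drop)
    recs <- recs[!drop]
    if (nrow(recs) == 0L || min(recs$logp) >= log_thr) {
      report["no_instrument"] <- report["no_instrument"] + 1L
      next
    }
    if (!is.null(mhc) && cs$probe$chrom == mhc$chrom &&
        cs$probe$bp >= mhc$start && cs$probe$bp <= mhc$end) {
      report["mhc"] <- report["mhc"] + 1L
      next
    }
    out[[id]] <- cis_summary(cs$probe, recs, cs$window_bp)
  }
  attr(out, "report") <- report
  out
}

#' Variance explained by a QTL from its z-statistic
#'
#' `r^2 = z^2 / (z^2 + n - 2)`, the squared sample correlation implied by
#' a t-like z-statistic at sample size n.
#'
#' @param z z-statistic.
#' @param n sample size (> 2).
#' @return fraction in \[0, 1).
#' @export
qtl_variance_explained <- function(z, n) {
  if (any(n <= 2)) stop("n must be > 2")
  z^2 / (z^2 + n - 2)
}
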