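## Multi-SNP SMR: combine ratio estimates at all significant cis SNPs in
## a set-based test accounting for LD.

#' Multi-SNP SMR test
#'
#' Selects all cis SNPs with exposure `p < p_instrument` (spec default
#' 5e-8) within the 500 kb multi-SNP window around the probe, prunes SNPs
#' in very high LD (`r^2 > multi_r2_prune`) with the top SNP (top SNP
#' kept), computes the per-SNP SMR z-statistics
#' `z_i = sign(b_xy(i)) sqrt(T_i)` and the statistic `T = sum z_i^2`.
#' Under the null `z ~ MVN(0, R)`, so `T` follows the weighted chi-square
#' form with weights the eigenvalues of `R`; the p-value comes from
#' [quadform_pvalue()].
#'
#' @param cis exposure `CisSummary` (harmonized with the outcome).
#' @param outcome aligned outcome summary table containing all cis SNPs.
#' @param panel `LdPanel`.
#' @param cfg configuration from [smr_config()]; uses `p_instrument` and
#'   `multi_r2_prune`.
#' @param panel_index harmonization flip table from [harmonize()] (sign
#'   alignment of the LD matrix).
#' @param window_bp multi-SNP selection half-window around the probe
#'   (default 500 kb).
#' @return list `p`, `t`, `n_snps`, `snps`; `p` is `NA` with
#'   `n_snps = 0` when no SNP is eligible.
#' @export
smr_multi <- function(cis, outcome, panel, cfg = smr_config(),
                      panel_index = NULL, window_bp = 5e5) {
  recs <- cis$records[abs(bp - cis$probe$bp) <= window_bp]
  elig <- recs[logp < log(cfg$p_instrument) & snp %in% panel$bim$snp]
  if (nrow(elig) == 0L)
    return(list(p = NA_real_, t = NA_real_, n_snps = 0L,
                snps = character(0)))
  data.table::setorder(elig, logp, bp, snp)
  top <- elig$snp[1]
  ids <- elig$snp
  flip <- if (is.null(panel_index)) NULL else
    panel_index$flip[match(ids, panel_index$snp)]
  R <- ld_matrix(panel, ids, flip = flip)
  keep <- R[top, ]^2 <= cfg$multi_r2_prune
  keep[top] <- TRUE
  ids <- ids[keep[ids]]
  R <- R[ids, ids, drop = FALSE]

  ex <- cis$records[match(ids, snp)]
  oy <- outcome[match(ids, snp)]
  z <- vapply(seq_along(ids), function(k) {
    fit <- smr_test(ex[k], oy[k])
    sign(fit$b_xy) * sqrt(fit$t_smr)
  }, numeric(1))
  t_stat <- sum(z^2)
  lam <- pmax(eigen(make_psd(R), symmetric = TRUE, only.values = TRUE)$values, 0)
  p <- quadform_pvalue(lam, t_stat)
  list(p = as.numeric(p), t = t_stat, n_snps = length(ids), snps = ids)
}
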