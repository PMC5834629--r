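# Shared builders for toy summary tables, panels and LD structures.

# summary table row(s) in the internal column layout
snp_tab <- function(snp, b, se, freq = 0.3, a1 = "A", a2 = "G",
                    chrom = "1", bp = seq_along(snp) * 1000L,
                    n = 1000, p = NULL) {
  if (is.null(p)) p <- pchisq((b / se)^2, 1, lower.tail = FALSE)
  data.table::data.table(
    snp = snp, chrom = chrom, bp = as.integer(bp), a1 = a1, a2 = a2,
    freq = freq, b = b, se = se, p = p, logp = log(p), n = n)
}

toy_probe <- function(id = "cg1", kind = "methylation", chrom = "1",
                      bp = 1000L, gene = "", strand = "+") {
  list(probe_id = id, kind = kind, chrom = chrom, bp = as.integer(bp),
       gene = gene, strand = strand)
}

# small panel with given dosage matrix
toy_panel <- function(geno, snp = sprintf("rs%02d", seq_len(ncol(geno))),
                      bp = seq_len(ncol(geno)) * 1000L,
                      a1 = "A", a2 = "G") {
  bim <- data.table::data.table(snp = snp, chrom = "1",
                                bp = as.integer(bp), a1 = a1, a2 = a2)
  ld_panel(geno, bim)
}

# AR(1) correlation matrix
ar1_R <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# Monte-Carlo tail probability of sum(w * chisq_1) reusing a draw pool.
# pool: ndraw x m matrix of chi-square(1) draws.
mc_quadform_p <- function(weights, t, pool) {
  stat <- as.vector(pool[, seq_along(weights), drop = FALSE] %*% weights)
  mean(stat > t)
}

# summary-level pleiotropy / linkage draw for HEIDI calibration:
# exposure affected by causal index c1, outcome by c2 (== c1 for
# pleiotropy), with top-SNP correlations sqrt(r2x) / sqrt(r2y).
heidi_sim_draw <- function(R, c1, c2, r2x, r2y, n_x, n_y,
                           freqs = rep(0.3, nrow(R))) {
  rho_x <- R[, c1] * sqrt(r2x)
  rho_y <- R[, c2] * sqrt(r2y)
  simulate_summary_pair(R, rho_x, rho_y, n_x, n_y, freqs)
}

# run HEIDI on one summary-level draw given panel-free LD matrix R
heidi_p_from_draw <- function(draw, R, cfg = smr_config()) {
  ex <- draw$exposure
  oy <- draw$outcome
  elig <- which(ex$logp < log(cfg$heidi_p_eligible))
  top <- elig[which.min(ex$logp[elig])]
  if (ex$logp[top] >= log(cfg$p_instrument)) return(NA_real_)
  r2 <- R[top, ]^2
  cand <- setdiff(which(ex$logp < log(cfg$heidi_p_eligible) &
                          r2 >= cfg$heidi_r2_min & r2 <= cfg$heidi_r2_max),
                  top)
  if (length(cand) < cfg$heidi_min_snps) return(NA_real_)
  cand <- cand[order(ex$logp[cand])][seq_len(min(length(cand),
                                                 cfg$heidi_max_snps))]
  ids <- c(top, cand)
  ctx <- heidi_cov(ex[ids], oy[ids], make_psd(R[ids, ids]),
                   p_eligible = cfg$heidi_p_eligible)
  heidi_test(ctx, min_snps = cfg$heidi_min_snps)$p_heidi
}
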