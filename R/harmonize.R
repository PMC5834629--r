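## Allele harmonization across exposure study, outcome study and LD panel.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Flip a summary record to the other allele
#'
#' Swaps effect/other allele, negates beta and replaces freq by 1 - freq.
#' Applying it twice restores the input exactly.
#'
#' @param dt summary table (internal columns).
#' @param idx rows to flip (default all).
#' @return flipped copy.
#' @export
flip_alleles <- function(dt, idx = seq_len(nrow(dt))) {
  out <- data.table::copy(dt)
  tmp <- out$a1[idx]
  out[idx, a1 := out$a2[idx]]
  out[idx, a2 := tmp]
  out[idx, b := -b]
  out[idx, freq := 1 - freq]
  out
}

#' Is a SNP strand-ambiguous (palindromic A/T or C/G)?
#' @param a1,a2 allele vectors.
#' @return logical vector.
#' @export
is_ambiguous <- function(a1, a2) {
  unname(.complement[a1] == a2 & !is.na(.complement[a1]))
}

#' Harmonize exposure, outcome and LD-panel alleles
#'
#' Keeps SNPs present in all three sources with consistent allele pairs,
#' aligns the outcome's effect allele to the exposure's (negating beta and
#' flipping freq on A1/A2 swaps), removes strand-ambiguous (A/T, C/G)
#' SNPs, and removes SNPs whose effect-allele frequency differs by more
#' than `freq_tol` between any pair of sources.
#'
#' @param exposure,outcome summary tables (internal columns).
#' @param panel an `LdPanel`, or `NULL` to harmonize two studies only.
#' @param freq_tol maximum allele-frequency discrepancy (default 0.2).
#' @param drop_ambiguous remove palindromic SNPs (default TRUE).
#' @return list with elements `exposure`, `outcome` (aligned tables in
#'   matching row order), `panel_index` (`data.table` of `snp` and `flip`,
#'   flip TRUE where the panel A1 is the exposure other allele; `NULL`
#'   when no panel given) and `report`, a named integer vector of
#'   exclusion counts.
#' @export
harmonize <- function(exposure, outcome, panel = NULL, freq_tol = 0.2,
                      drop_ambiguous = TRUE) {
  exp <- data.table::copy(exposure)
  out <- data.table::copy(outcome)
  report <- c(not_shared = 0L, allele_mismatch = 0L,
              strand_ambiguous = 0L, freq_mismatch = 0L)

  shared <- intersect(exp$snp, out$snp)
  if (!is.null(panel)) shared <- intersect(shared, panel$bim$snp)
  report["not_shared"] <- length(unique(c(exp$snp, out$snp))) - length(shared)
  exp <- exp[snp %in% shared]
  out <- out[match(exp$snp, out$snp)]

  ## outcome alignment
  same <- out$a1 == exp$a1 & out$a2 == exp$a2
  swap <- out$a1 == exp$a2 & out$a2 == exp$a1
  bad <- !(same | swap)
  if (any(swap)) out <- flip_alleles(out, which(swap))

  ## panel alignment
  pflip <- rep(FALSE, nrow(exp))
  pfreq <- rep(NA_real_, nrow(exp))
  if (!is.null(panel)) {
    pb <- panel$bim[match(exp$snp, panel$bim$snp)]
    psame <- pb$a1 == exp$a1 & pb$a2 == exp$a2
    pswap <- pb$a1 == exp$a2 & pb$a2 == exp$a1
    bad <- bad | !(psame | pswap)
    pflip <- pswap
    pf <- panel_freq(panel, exp$snp)
    pfreq <- ifelse(pswap, 1 - pf, pf)
  }
  report["allele_mismatch"] <- sum(bad)

  amb <- rep(FALSE, nrow(exp))
  if (drop_ambiguous) amb <- is_ambiguous(exp$a1, exp$a2) & !bad
  report["strand_ambiguous"] <- sum(amb)

  fmis <- abs(exp$freq - out$freq) > freq_tol
  if (!is.null(panel))
    fmis <- fmis | abs(exp$freq - pfreq) > freq_tol |
      abs(out$freq - pfreq) > freq_tol
  fmis <- fmis & !bad & !amb
  report["freq_mismatch"] <- sum(fmis)

  keep <- !(bad | amb | fmis)
  if (!any(keep))
    stop("empty intersection: no SNP survives harmonization")
  exp <- exp[keep]
  out <- out[keep]
  pidx <- NULL
  if (!is.null(panel))
    pidx <- data.table::data.table(snp = exp$snp, flip = pflip[keep])
  list(exposure = exp, outcome = out, panel_index = pidx, report = report)
}
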