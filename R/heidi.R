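## HEIDI: heterogeneity in dependent instruments.
##
## Under pleiotropy (one shared causal variant) the ratio estimate b_xy is
## the same at every SNP in LD with the causal variant, so the deviations
## d_i = b_xy(i) - b_xy(top) are jointly MVN around zero. Linkage (distinct
## causal variants) makes the d_i drift away from zero. The test statistic
## is the sum of squared standardized deviations; its null distribution is
## a weighted sum of 1-df chi-squares with weights the eigenvalues of the
## correlation matrix of d.

#' Select the SNPs entering the HEIDI test
#'
#' Candidates need exposure `p < p_eligible` and squared correlation with
#' the instrument inside `[r2_min, r2_max]` — SNPs in near-perfect LD
#' carry no independent information and nearly independent SNPs are weak
#' instruments. Candidates are ranked by exposure significance and
#' truncated to `max_snps`; the instrument is prepended.
#'
#' @param cis exposure `CisSummary` (harmonized records).
#' @param panel `LdPanel`.
#' @param instrument instrument SNP id (must be in `cis`).
#' @param p_eligible eligibility threshold (default 1.57e-3).
#' @param r2_min,r2_max LD window vs the instrument (defaults 0.05, 0.9).
#' @param max_snps cap on non-instrument SNPs (default 20).
#' @param panel_index optional harmonization flip table (ignored: r^2 is
#'   sign-free); accepted for interface symmetry.
#' @return character vector of SNP ids, instrument first.
#' @export
select_heidi_snps <- function(cis, panel, instrument,
                              p_eligible = 1.57e-3,
                              r2_min = 0.05, r2_max = 0.9,
                              max_snps = 20L, panel_index = NULL) {
  recs <- cis$records
  if (!instrument %in% recs$snp)
    stop("instrument ", instrument, " not in cis records")
  cand <- recs[snp != instrument & logp < log(p_eligible)]
  cand <- cand[snp %in% panel$bim$snp]
  if (nrow(cand) == 0L) return(instrument)
  R <- ld_matrix(panel, c(instrument, cand$snp))
  r2 <- R[1, -1]^2
  cand <- cand[r2 >= r2_min & r2 <= r2_max]
  if (nrow(cand) == 0L) return(instrument)
  data.table::setorder(cand, logp, bp, snp)
  c(instrument, head(cand$snp, max_snps))
}

#' Build the HEIDI context (d vector and its covariance)
#'
#' Computes per-SNP ratio estimates `b_xy(i) = b_zy(i)/b_zx(i)`, their
#' first-order delta-method covariance assuming independent exposure and
#' outcome studies sharing LD matrix `R`,
#' `cov(b_xy(i), b_xy(j)) = R_ij se_zy(i) se_zy(j) / (b_zx(i) b_zx(j)) +
#'  R_ij b_zy(i) b_zy(j) se_zx(i) se_zx(j) / (b_zx(i)^2 b_zx(j)^2)`,
#' and the covariance `V` of `d_i = b_xy(i) - b_xy(0)`.
#'
#' @param exposure,outcome aligned summary tables for the selected SNPs,
#'   row 1 = instrument.
#' @param R LD correlation matrix in the same order.
#' @param p_eligible weak-instrument guard: every exposure z must exceed
#'   the z equivalent of this p-value (default 1.57e-3).
#' @return object of class `HeidiContext`: list with `snp_ids`, `d`
#'   (length m-1), `V` ((m-1) x (m-1)), `weights` (eigenvalues of the
#'   correlation matrix of d, clipped at zero).
#' @export
heidi_cov <- function(exposure, outcome, R, p_eligible = 1.57e-3) {
  m <- nrow(exposure)
  stopifnot(nrow(outcome) == m, all(dim(R) == m))
  if (m < 2L) stop("heidi_cov needs at least 2 SNPs")
  bx <- exposure$b; sx <- exposure$se
  by <- outcome$b;  sy <- outcome$se
  z_min <- sqrt(qchisq(p_eligible, df = 1, lower.tail = FALSE))
  if (any(abs(bx / sx) < z_min))
    stop("weak instrument: exposure |z| below eligibility for ",
         paste(exposure$snp[abs(bx / sx) < z_min], collapse = ", "))

  bxy <- by / bx
  ## cov(b_xy(i), b_xy(j)), all pairs including the instrument (index 1)
  C <- R * (tcrossprod(sy) / tcrossprod(bx)) +
       R * (tcrossprod(by) * tcrossprod(sx) / tcrossprod(bx^2))
  i <- 2:m
  V <- C[i, i, drop = FALSE] -
    matrix(C[i, 1], m - 1L, m - 1L) -
    matrix(C[1, i], m - 1L, m - 1L, byrow = TRUE) +
    C[1, 1]
  V <- (V + t(V)) / 2
  d <- bxy[i] - bxy[1]

  Dc <- stats::cov2cor(V)
  ev <- eigen(Dc, symmetric = TRUE, only.values = TRUE)$values
  weights <- pmax(ev, 0)
  structure(list(snp_ids = exposure$snp, d = d, V = V, weights = weights),
            class = "HeidiContext")
}

#' HEIDI heterogeneity test
#'
#' `t = sum_i (d_i / sqrt(V_ii))^2`; the null distribution is the
#' weighted chi-square form with weights the eigenvalues of the
#' correlation matrix of d, evaluated by [quadform_pvalue()].
#'
#' @param ctx a `HeidiContext` from [heidi_cov()].
#' @param min_snps minimum number of non-instrument SNPs (default 3);
#'   below it the p-value is `NA` with status `heidi_insufficient_snps`.
#' @return list `p_heidi`, `n_heidi_snps`, `t_heidi`, `status`.
#' @export
heidi_test <- function(ctx, min_snps = 3L) {
  m <- length(ctx$d)
  if (m < min_snps)
    return(list(p_heidi = NA_real_, n_heidi_snps = m, t_heidi = NA_real_,
                status = "heidi_insufficient_snps"))
  zd <- ctx$d / sqrt(diag(ctx$V))
  t_heidi <- sum(zd^2)
  p <- quadform_pvalue(ctx$weights, t_heidi)
  list(p_heidi = as.numeric(p), n_heidi_snps = m, t_heidi = t_heidi,
       status = "ok")
}
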