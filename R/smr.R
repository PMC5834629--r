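## Single-instrument SMR: ratio estimate, delta-method Wald test.

#' Default analysis configuration
#'
#' Central knob set shared by the SMR drivers and the pipeline. All
#' thresholds can be overridden via `...`.
#'
#' @param ... named overrides.
#' @return named list of parameters: `p_instrument` (instrument
#'   significance, 5e-8), `heidi_p_eligible` (SNP eligibility for HEIDI,
#'   1.57e-3), `heidi_r2_min`/`heidi_r2_max` (LD pruning window vs the
#'   instrument, 0.05/0.9), `heidi_max_snps` (20), `heidi_min_snps`
#'   (minimum non-instrument SNPs, 3), `heidi_p_threshold` (HEIDI filter,
#'   0.01), `multi_r2_prune` (SMR-multi pruning vs top SNP, 0.9),
#'   `window_bp` (cis window for trait scans, 2 Mb), `pair_window_bp`
#'   (M2T probe-pair window, 2 Mb), `freq_tol` (harmonization, 0.2),
#'   `min_maf` (0.01), `alpha` (0.05), `strict_heidi` (treat
#'   HEIDI-not-run as fail, TRUE), `multi` (run SMR-multi, FALSE).
#' @export
smr_config <- function(...) {
  cfg <- list(
    p_instrument = 5e-8,
    heidi_p_eligible = 1.57e-3,
    heidi_r2_min = 0.05,
    heidi_r2_max = 0.9,
    heidi_max_snps = 20L,
    heidi_min_snps = 3L,
    heidi_p_threshold = 0.01,
    multi_r2_prune = 0.9,
    window_bp = 2e6,
    pair_window_bp = 2e6,
    freq_tol = 0.2,
    min_maf = 0.01,
    alpha = 0.05,
    strict_heidi = TRUE,
    multi = FALSE)
  ovr <- list(...)
  if (length(ovr)) {
    unknown <- setdiff(names(ovr), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, ovr)
  }
  cfg
}

#' Select the instrument SNP for a probe
#'
#' The most significant cis SNP, provided it passes `p_threshold`.
#' Ties on p are broken by smaller bp, then lexicographic SNP id, for
#' determinism.
#'
#' @param cis a `CisSummary`.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @return one-row `data.table`, or `NULL` when no SNP qualifies.
#' @export
select_instrument <- function(cis, p_threshold = 5e-8) {
  recs <- cis$records
  if (nrow(recs) == 0L) return(NULL)
  elig <- recs[logp < log(p_threshold)]
  if (nrow(elig) == 0L) return(NULL)
  data.table::setorder(elig, logp, bp, snp)
  elig[1]
}

#' Single-SNP SMR test
#'
#' Ratio (Wald) estimate of the exposure effect on the outcome using one
#' genetic instrument: `b_xy = b_zy / b_zx`. The first-order delta-method
#' Wald statistic has the closed form
#' `T = z_zy^2 z_zx^2 / (z_zy^2 + z_zx^2)` with `z = b / se`; the SE is
#' recovered as `|b_xy| / sqrt(T)` and `P` is the chi-square(1) survival
#' probability at `T`.
#'
#' @param zx instrument record in the exposure study (list/1-row table
#'   with `snp, a1, a2, b, se`).
#' @param zy same SNP in the outcome study, alleles already aligned.
#' @return list `b_xy, se_xy, t_smr, p_smr, logp_smr`.
#' @export
smr_test <- function(zx, zy) {
  zx <- as.list(zx); zy <- as.list(zy)
  if (!identical(zx$snp, zy$snp))
    stop("smr_test: instrument mismatch (", zx$snp, " vs ", zy$snp, ")")
  if (!identical(zx$a1, zy$a1) || !identical(zx$a2, zy$a2))
    stop("smr_test: alleles not aligned for ", zx$snp)
  z1 <- zx$b / zx$se
  z2 <- zy$b / zy$se
  t_smr <- z2^2 * z1^2 / (z2^2 + z1^2)
  b_xy <- zy$b / zx$b
  se_xy <- abs(b_xy) / sqrt(t_smr)
  logp <- pchisq(t_smr, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr,
       p_smr = exp(logp), logp_smr = logp)
}

#' SMR + HEIDI for one exposure probe against one outcome
#'
#' Full per-probe driver: harmonizes the probe's cis records with the
#' outcome summary table and the LD panel, selects the instrument, runs
#' the SMR test, the HEIDI test and (optionally) SMR-multi.
#'
#' @param cis exposure `CisSummary` (already QC-filtered).
#' @param outcome outcome summary table (internal columns): either a GWAS
#'   table or another probe's cis records.
#' @param panel `LdPanel`.
#' @param cfg configuration from [smr_config()].
#' @param exposure_id,outcome_id identifiers copied to the result row.
#' @return one-row `data.table` with columns `exposure_id, outcome_id,
#'   instrument, b_xy, se_xy, p_smr, logp_smr, p_heidi, n_heidi_snps,
#'   p_smr_multi, n_multi_snps, status`.
#' @export
smr_probe <- function(cis, outcome, panel, cfg = smr_config(),
                      exposure_id = cis$probe$probe_id,
                      outcome_id = "outcome") {
  empty <- data.table::data.table(
    exposure_id = exposure_id, outcome_id = outcome_id,
    instrument = NA_character_, b_xy = NA_real_, se_xy = NA_real_,
    p_smr = NA_real_, logp_smr = NA_real_, p_heidi = NA_real_,
    n_heidi_snps = 0L, p_smr_multi = NA_real_, n_multi_snps = 0L,
    status = "no_instrument")

  h <- tryCatch(
    harmonize(cis$records, outcome, panel, freq_tol = cfg$freq_tol),
    error = function(e) NULL)
  if (is.null(h)) return(empty)
  hcis <- cis_summary(cis$probe, h$exposure, cis$window_bp)

  inst <- select_instrument(hcis, cfg$p_instrument)
  if (is.null(inst)) return(empty)
  zy <- h$outcome[snp == inst$snp]
  fit <- smr_test(inst, zy)

  ## HEIDI
  p_heidi <- NA_real_
  n_heidi <- 0L
  status <- "ok"
  hs <- tryCatch(
    select_heidi_snps(hcis, panel, inst$snp,
                      p_eligible = cfg$heidi_p_eligible,
                      r2_min = cfg$heidi_r2_min, r2_max = cfg$heidi_r2_max,
                      max_snps = cfg$heidi_max_snps,
                      panel_index = h$panel_index),
    error = function(e) character(0))
  if (length(hs) >= cfg$heidi_min_snps + 1L) {
    ids <- hs
    flip <- h$panel_index$flip[match(ids, h$panel_index$snp)]
    R <- make_psd(ld_matrix(panel, ids, flip = flip))
    ctx <- heidi_cov(h$exposure[match(ids, snp)], h$outcome[match(ids, snp)],
                     R, p_eligible = cfg$heidi_p_eligible)
    ht <- heidi_test(ctx, min_snps = cfg$heidi_min_snps)
    p_heidi <- ht$p_heidi
    n_heidi <- ht$n_heidi_snps
    if (is.na(p_heidi)) status <- "heidi_insufficient_snps"
  } else {
    status <- "heidi_insufficient_snps"
    n_heidi <- max(0L, length(hs) - 1L)
  }

  ## SMR-multi
  p_multi <- NA_real_
  n_multi <- 0L
  if (isTRUE(cfg$multi)) {
    sm <- smr_multi(hcis, h$outcome, panel, cfg = cfg,
                    panel_index = h$panel_index)
    p_multi <- sm$p
    n_multi <- sm$n_snps
  }

  data.table::data.table(
    exposure_id = exposure_id, outcome_id = outcome_id,
    instrument = inst$snp, b_xy = fit$b_xy, se_xy = fit$se_xy,
    p_smr = fit$p_smr, logp_smr = fit$logp_smr, p_heidi = p_heidi,
    n_heidi_snps = n_heidi, p_smr_multi = p_multi, n_multi_snps = n_multi,
    status = status)
}
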