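## The three-step integration pipeline: methylome -> transcriptome (M2T,
## and the reversed T2M direction), omics -> trait, triplet combination
## and descriptive statistics of the resulting map.

#' Bonferroni threshold
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / n_tests
}

## Attach pass flags: Bonferroni over the realized test count, HEIDI at
## cfg$heidi_p_threshold. In strict mode a pair where HEIDI could not run
## is conservatively not passed.
.assoc_flags <- function(tab, cfg) {
  if (nrow(tab) == 0L) {
    tab[, `:=`(bonferroni_pass = logical(0), heidi_pass = logical(0),
               pass = logical(0))]
    return(tab)
  }
  thr <- bonferroni_threshold(cfg$alpha, nrow(tab))
  tab[, bonferroni_pass := !is.na(logp_smr) & logp_smr < log(thr)]
  if (isTRUE(cfg$strict_heidi)) {
    tab[, heidi_pass := !is.na(p_heidi) & p_heidi >= cfg$heidi_p_threshold]
  } else {
    tab[, heidi_pass := is.na(p_heidi) | p_heidi >= cfg$heidi_p_threshold]
  }
  tab[, pass := bonferroni_pass & heidi_pass]
  data.table::setattr(tab, "bonferroni_threshold", thr)
  tab
}

## Run SMR+HEIDI for every (exposure probe, outcome probe) pair within
## the pair window. Shared by run_m2t / run_t2m.
.run_pairs <- function(exposure_list, outcome_list, panel, cfg) {
  epos <- data.table::rbindlist(lapply(exposure_list, function(cs)
    data.table::data.table(probe_id = cs$probe$probe_id,
                           chrom = cs$probe$chrom, bp = cs$probe$bp)))
  opos <- data.table::rbindlist(lapply(outcome_list, function(cs)
    data.table::data.table(probe_id = cs$probe$probe_id,
                           chrom = cs$probe$chrom, bp = cs$probe$bp,
                           gene = cs$probe$gene)))
  rows <- list()
  for (i in seq_len(nrow(epos))) {
    e <- epos[i]
    cand <- opos[chrom == e$chrom & abs(bp - e$bp) <= cfg$pair_window_bp]
    for (j in seq_len(nrow(cand))) {
      cs <- exposure_list[[e$probe_id]]
      oc <- outcome_list[[cand$probe_id[j]]]
      res <- smr_probe(cs, oc$records, panel, cfg,
                       exposure_id = e$probe_id,
                       outcome_id = cand$probe_id[j])
      res[, `:=`(exposure_chrom = e$chrom, exposure_bp = e$bp,
                 outcome_chrom = cand$chrom[j], outcome_bp = cand$bp[j],
                 outcome_gene = cand$gene[j])]
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    warning("no probe pairs within the pair window: empty result")
    return(.assoc_flags(.empty_assoc(), cfg))
  }
  tab <- data.table::rbindlist(rows)
  data.table::setorder(tab, exposure_id, outcome_id)
  .assoc_flags(tab, cfg)
}

.empty_assoc <- function() {
  data.table::data.table(
    exposure_id = character(0), outcome_id = character(0),
    instrument = character(0), b_xy = numeric(0), se_xy = numeric(0),
    p_smr = numeric(0), logp_smr = numeric(0), p_heidi = numeric(0),
    n_heidi_snps = integer(0), p_smr_multi = numeric(0),
    n_multi_snps = integer(0), status = character(0),
    exposure_chrom = character(0), exposure_bp = integer(0),
    outcome_chrom = character(0), outcome_bp = integer(0),
    outcome_gene = character(0))
}

#' Methylome-to-transcriptome scan (M2T)
#'
#' Tests every DNAm probe against every expression probe within the pair
#' window (default 2 Mb) on the same chromosome, DNAm as exposure with
#' the top mQTL as instrument. Bonferroni correction uses the realized
#' pair count; the HEIDI filter keeps pairs with
#' `p_heidi >= cfg$heidi_p_threshold`.
#'
#' @param mqtl named list of methylation `CisSummary` (QC-filtered).
#' @param eqtl named list of expression `CisSummary`.
#' @param panel `LdPanel`.
#' @param cfg configuration from [smr_config()].
#' @return association `data.table` with pass flags; the realized
#'   Bonferroni threshold is in `attr(x, "bonferroni_threshold")`.
#' @export
run_m2t <- function(mqtl, eqtl, panel, cfg = smr_config()) {
  .run_pairs(mqtl, eqtl, panel, cfg)
}

#' Transcriptome-to-methylome scan (T2M)
#'
#' As [run_m2t()] with the roles reversed: expression is the exposure
#' (top eQTL instrument), DNAm the outcome.
#'
#' @inheritParams run_m2t
#' @return association `data.table` with pass flags.
#' @export
run_t2m <- function(eqtl, mqtl, panel, cfg = smr_config()) {
  .run_pairs(eqtl, mqtl, panel, cfg)
}

#' Overlap report between two association scans
#'
#' Pairs are matched irrespective of direction (the M2T pair
#' (methylation probe, expression probe) equals the T2M pair with roles
#' swapped).
#'
#' @param m2t,t2m association tables from [run_m2t()] and [run_t2m()].
#' @param passing_only compare only passing pairs (default TRUE).
#' @return list `both`, `first_only`, `second_only` of pair keys.
#' @export
overlap_report <- function(m2t, t2m, passing_only = TRUE) {
  key1 <- m2t[if (passing_only) pass else TRUE,
              paste(exposure_id, outcome_id, sep = "|")]
  key2 <- t2m[if (passing_only) pass else TRUE,
              paste(outcome_id, exposure_id, sep = "|")]
  list(both = intersect(key1, key2),
       first_only = setdiff(key1, key2),
       second_only = setdiff(key2, key1))
}

#' Omics-to-trait scan
#'
#' Tests each probe (expression or methylation) against one GWAS outcome.
#' Bonferroni correction uses the realized probe count.
#'
#' @param qtl named list of `CisSummary` (QC-filtered).
#' @param gwas GWAS summary table (internal columns) from
#'   [read_gwas_ma()].
#' @param panel `LdPanel`.
#' @param cfg configuration from [smr_config()]; set `multi = TRUE` to
#'   add the SMR-multi p-value column.
#' @param trait_id outcome label (default "trait").
#' @return association `data.table` with pass flags.
#' @export
run_omics_trait <- function(qtl, gwas, panel, cfg = smr_config(),
                            trait_id = "trait") {
  rows <- lapply(names(qtl), function(id) {
    cs <- qtl[[id]]
    res <- smr_probe(cs, gwas, panel, cfg, exposure_id = id,
                     outcome_id = trait_id)
    res[, `:=`(exposure_chrom = cs$probe$chrom, exposure_bp = cs$probe$bp,
               outcome_chrom = NA_character_, outcome_bp = NA_integer_,
               outcome_gene = NA_character_)]
    res
  })
  if (length(rows) == 0L) {
    warning("no probes to test: empty result")
    return(.assoc_flags(.empty_assoc(), cfg))
  }
  tab <- data.table::rbindlist(rows)
  data.table::setorder(tab, exposure_id)
  .assoc_flags(tab, cfg)
}

#' Combine the three scans into DNAm-gene-trait triplets
#'
#' Inner join on (DNAm probe, expression probe, trait), keeping triplets
#' where all three associations pass both the Bonferroni and the HEIDI
#' filter.
#'
#' @param m2t DNAm-vs-expression associations ([run_m2t()]).
#' @param m2trait DNAm-vs-trait associations ([run_omics_trait()]).
#' @param t2trait expression-vs-trait associations.
#' @return `data.table`, one row per passing triplet, with the three
#'   (p_smr, p_heidi) pairs.
#' @export
combine_triplets <- function(m2t, m2trait, t2trait) {
  a <- m2t[pass == TRUE,
           .(dnam_probe = exposure_id, gene_probe = outcome_id,
             b_xy_m2t = b_xy, p_smr_m2t = p_smr, p_heidi_m2t = p_heidi)]
  b <- m2trait[pass == TRUE,
               .(dnam_probe = exposure_id, trait = outcome_id,
                 b_xy_m2trait = b_xy, p_smr_m2trait = p_smr,
                 p_heidi_m2trait = p_heidi)]
  cc <- t2trait[pass == TRUE,
                .(gene_probe = exposure_id, trait = outcome_id,
                  b_xy_t2trait = b_xy, p_smr_t2trait = p_smr,
                  p_heidi_t2trait = p_heidi)]
  if (nrow(a) == 0L || nrow(b) == 0L || nrow(cc) == 0L)
    return(data.table::data.table(
      dnam_probe = character(0), gene_probe = character(0),
      trait = character(0), b_xy_m2t = numeric(0), p_smr_m2t = numeric(0),
      p_heidi_m2t = numeric(0), b_xy_m2trait = numeric(0),
      p_smr_m2trait = numeric(0), p_heidi_m2trait = numeric(0),
      b_xy_t2trait = numeric(0), p_smr_t2trait = numeric(0),
      p_heidi_t2trait = numeric(0)))
  out <- merge(a, b, by = "dnam_probe", allow.cartesian = TRUE)
  out <- merge(out, cc, by = c("gene_probe", "trait"))
  data.table::setcolorder(out, c("dnam_probe", "gene_probe", "trait"))
  data.table::setorder(out, dnam_probe, gene_probe, trait)
  out[]
}

#' Compare variance explained by an instrument in two molecular layers
#'
#' `delta_r2 = r2_e - r2_m` via [qtl_variance_explained()]; the p-value
#' is a two-sided normal test on the difference of Fisher-z transformed
#' correlations with variances `1/(n-3)`.
#'
#' @param z_e,n_e instrument z and sample size in the expression study.
#' @param z_m,n_m instrument z and sample size in the methylation study.
#' @return list `delta_r2`, `p`.
#' @export
variance_comparison <- function(z_e, n_e, z_m, n_m) {
  if (n_e <= 3 || n_m <= 3) stop("n must be > 3")
  r_e <- z_e / sqrt(z_e^2 + n_e - 2)
  r_m <- z_m / sqrt(z_m^2 + n_m - 2)
  delta_r2 <- r_e^2 - r_m^2
  stat <- (atanh(r_e) - atanh(r_m)) / sqrt(1 / (n_e - 3) + 1 / (n_m - 3))
  p <- 2 * pnorm(-abs(stat))
  list(delta_r2 = delta_r2, p = p)
}

#' Nearest-gene mapping proportions
#'
#' For each DNAm probe with at least one passing gene association,
#' determines whether its associated gene set contains the physically
#' nearest annotated gene. Returns `pi_nearest` (fraction of probes
#' mapped to their nearest gene, alone or together with distal genes),
#' `pi_distal` (fraction mapped to at least one non-nearest gene) and
#' `pi_both` (fraction mapped to both). Nearest = minimal
#' `|gene bp - probe bp|` among expression probes on the chromosome,
#' distance ties broken toward smaller bp.
#'
#' @param m2t M2T association table (only passing rows are used).
#' @param annotations probe annotation table covering the expression
#'   probes (gene positions are taken from rows with
#'   `kind == "expression"`).
#' @param restrict_to_tested_nearest drop probes whose nearest gene is
#'   not among the genes tested for that probe (default FALSE).
#' @return list `pi_nearest, pi_distal, pi_both, n_probes, n_excluded`.
#' @export
nearest_gene_stats <- function(m2t, annotations,
                               restrict_to_tested_nearest = FALSE) {
  genes <- annotations[kind == "expression",
                       .(gene_probe = probe_id, chrom, bp,
                         gene = ifelse(gene == "", probe_id, gene))]
  sig <- m2t[pass == TRUE]
  if (nrow(sig) == 0L) stop("no passing associations")
  probes <- unique(sig[, .(exposure_id, exposure_chrom, exposure_bp)])

  n_excluded <- 0L
  cls <- character(0)
  for (i in seq_len(nrow(probes))) {
    pr <- probes[i]
    cand <- genes[chrom == pr$exposure_chrom]
    if (nrow(cand) == 0L) { n_excluded <- n_excluded + 1L; next }
    cand[, dist := abs(bp - pr$exposure_bp)]
    data.table::setorder(cand, dist, bp)
    nearest_gene <- cand$gene[1]
    mapped <- sig[exposure_id == pr$exposure_id]
    mapped_genes <- unique(ifelse(mapped$outcome_gene == "" |
                                    is.na(mapped$outcome_gene),
                                  mapped$outcome_id, mapped$outcome_gene))
    if (restrict_to_tested_nearest) {
      tested <- m2t[exposure_id == pr$exposure_id]
      tested_genes <- unique(ifelse(tested$outcome_gene == "" |
                                      is.na(tested$outcome_gene),
                                    tested$outcome_id, tested$outcome_gene))
      if (!nearest_gene %in% tested_genes) {
        n_excluded <- n_excluded + 1L
        next
      }
    }
    has_nearest <- nearest_gene %in% mapped_genes
    has_distal <- length(setdiff(mapped_genes, nearest_gene)) > 0L
    cls <- c(cls, if (has_nearest && has_distal) "both"
                  else if (has_nearest) "nearest" else "distal")
  }
  n <- length(cls)
  if (n == 0L) stop("no classifiable probes")
  list(pi_nearest = mean(cls %in% c("nearest", "both")),
       pi_distal = mean(cls %in% c("distal", "both")),
       pi_both = mean(cls == "both"),
       n_probes = n, n_excluded = n_excluded)
}

#' Within-gene direction concordance of DNAm effects
#'
#' Over all genes associated with at least two DNAm probes, the fraction
#' of within-gene DNAm-probe pairs whose `b_xy` signs agree (pairs pooled
#' across genes).
#'
#' @param m2t M2T association table (passing rows are used).
#' @return fraction in \[0, 1\].
#' @export
direction_concordance <- function(m2t) {
  sig <- m2t[pass == TRUE]
  agree <- 0L
  total <- 0L
  for (g in unique(sig$outcome_id)) {
    s <- sign(sig[outcome_id == g, b_xy])
    if (length(s) < 2L) next
    pairs <- utils::combn(s, 2L)
    agree <- agree + sum(pairs[1, ] == pairs[2, ])
    total <- total + ncol(pairs)
  }
  if (total == 0L)
    stop("no gene with >= 2 associated DNAm probes")
  agree / total
}
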