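## Coupled genotype/DNAm/expression/trait simulator.
##
## Three independent samples (mQTL study, eQTL study, GWAS) observe
## phenotypes generated from shared SNP metadata under one of four causal
## models; marginal per-SNP regressions then produce exactly the summary
## statistics the rest of the package consumes. All phenotypes are scaled
## by their theoretical SD so the implied exposure-on-outcome effects are
## exact products of path coefficients.

#' Simulation configuration
#'
#' @param model causal model: `mediation` (SNP -> DNAm -> expression ->
#'   trait), `pleiotropy` (one SNP directly affects all three layers,
#'   marginal effect sizes matched to the mediation model), `linkage`
#'   (a second SNP in LD with the first drives the downstream layers) or
#'   `null` (no links).
#' @param n_mqtl,n_eqtl,n_gwas,n_panel sample sizes of the three studies
#'   and the LD reference panel. Defaults (2000 / 2000 / 10000 / 500) are
#'   desk-scale stand-ins for a large mQTL meta-analysis, a blood eQTL
#'   consortium, a GWAS meta-analysis and a reference cohort.
#' @param n_snps SNPs at the locus (default 30, 5 kb spacing).
#' @param maf_range per-SNP MAF drawn uniformly from this range.
#' @param ld_decay adjacent-SNP correlation of the latent Gaussians in
#'   \[0, 1); default 0.9 gives realistic cis-window LD.
#' @param b_zm SNP -> DNAm path coefficient in DNAm-SD units per allele
#'   (default 0.5, top-mQTL r2 near 10 percent).
#' @param b_me DNAm -> expression path coefficient (default 1.0).
#' @param b_et expression -> trait path coefficient (default 0.5).
#' @param b_zx2 direct effect of the second causal SNP on the downstream
#'   layers under linkage; `NULL` (default) matches the mediation-implied
#'   marginals.
#' @param linkage_r2 target LD r2 between the two causal SNPs
#'   (default 0.2).
#' @param n_null_dnam,n_null_expr additional pure-noise probes measured
#'   in the same samples (default 1 each).
#' @param disease simulate a liability-threshold disease outcome with
#'   logistic (log odds-ratio) GWAS summaries instead of a quantitative
#'   trait (default FALSE).
#' @param prevalence disease prevalence for the liability threshold.
#' @param seed integer RNG seed.
#' @return classed list `SimConfig`.
#' @export
sim_config <- function(model = c("mediation", "pleiotropy", "linkage", "null"),
                       n_mqtl = 2000L, n_eqtl = 2000L, n_gwas = 10000L,
                       n_panel = 500L, n_snps = 30L,
                       maf_range = c(0.1, 0.5), ld_decay = 0.9,
                       b_zm = 0.5, b_me = 1.0, b_et = 0.5,
                       b_zx2 = NULL, linkage_r2 = 0.2,
                       n_null_dnam = 1L, n_null_expr = 1L,
                       disease = FALSE, prevalence = 0.1, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_mqtl >= 10, n_eqtl >= 10, n_gwas >= 10, n_panel >= 10,
            ld_decay >= 0, ld_decay < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (model == "linkage" && !is.null(b_zx2) && b_zx2 == 0)
    stop("linkage model requires a nonzero second-variant effect")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate genotype dosages at a locus
#'
#' Two latent AR(1) Gaussian gametes per individual are thresholded at
#' the per-SNP MAF quantile and summed, yielding Hardy-Weinberg dosages
#' whose LD decays with inter-SNP distance.
#'
#' @param n individuals.
#' @param mafs per-SNP minor (effect) allele frequencies.
#' @param ld_decay adjacent-SNP latent correlation.
#' @return integer matrix n x length(mafs) with values 0/1/2 counting the
#'   effect allele.
#' @export
simulate_genotypes <- function(n, mafs, ld_decay = 0.9) {
  m <- length(mafs)
  gamete <- function() {
    z <- matrix(rnorm(n * m), n, m)
    if (ld_decay > 0 && m > 1) {
      for (k in 2:m)
        z[, k] <- ld_decay * z[, k - 1] + sqrt(1 - ld_decay^2) * z[, k]
    }
    sweep(z, 2, qnorm(mafs), "<") * 1L
  }
  g <- gamete() + gamete()
  storage.mode(g) <- "integer"
  g
}

#' Per-SNP marginal regression summary statistics
#'
#' Simple OLS of the phenotype on each dosage column (with intercept);
#' p-values from the Wald chi-square.
#'
#' @param geno dosage matrix (n x m).
#' @param pheno numeric phenotype vector.
#' @param bim SNP metadata table (`snp, chrom, bp, a1, a2`).
#' @return summary table in internal columns.
#' @export
marginal_stats <- function(geno, pheno, bim) {
  n <- length(pheno)
  gc <- scale(geno, center = TRUE, scale = FALSE)
  yc <- pheno - mean(pheno)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  syy <- sum(yc^2)
  b <- sxy / sxx
  resvar <- pmax(syy - b * sxy, 0) / (n - 2)
  se <- sqrt(resvar / sxx)
  logp <- pchisq((b / se)^2, df = 1, lower.tail = FALSE, log.p = TRUE)
  data.table::data.table(
    snp = bim$snp, chrom = bim$chrom, bp = bim$bp, a1 = bim$a1,
    a2 = bim$a2, freq = colMeans(geno) / 2, b = b, se = se,
    p = exp(logp), logp = logp, n = as.numeric(n))
}

## logistic per-SNP summaries for disease outcomes (log odds-ratios)
.marginal_logistic <- function(geno, case, bim) {
  n <- length(case)
  fit1 <- function(g) {
    m <- glm(case ~ g, family = binomial())
    cf <- summary(m)$coefficients
    c(cf["g", "Estimate"], cf["g", "Std. Error"])
  }
  est <- apply(geno, 2, fit1)
  b <- est[1, ]; se <- est[2, ]
  logp <- pchisq((b / se)^2, df = 1, lower.tail = FALSE, log.p = TRUE)
  data.table::data.table(
    snp = bim$snp, chrom = bim$chrom, bp = bim$bp, a1 = bim$a1,
    a2 = bim$a2, freq = colMeans(geno) / 2, b = b, se = se,
    p = exp(logp), logp = logp, n = as.numeric(n))
}

## standardize a raw phenotype by its theoretical SD
.std <- function(raw, var_theory) raw / sqrt(var_theory)

#' Simulate a coupled three-study dataset with summary statistics
#'
#' Draws three disjoint samples plus an LD panel at one locus and
#' generates, per study, the marginal summary statistics of every SNP on
#' the phenotype observed in that study: DNAm in the mQTL study,
#' expression in the eQTL study, the trait in the GWAS.
#'
#' @param cfg a [sim_config()].
#' @return list with `mqtl`, `eqtl` (named lists of `CisSummary`),
#'   `gwas` (summary table), `panel` (`LdPanel`), `annotations` (probe
#'   annotation table), `truth` (`SimTruth`: model, causal indices,
#'   implied b_xy per exposure-outcome pair, expected top-QTL r2 per
#'   layer) and `bim`.
#' @export
simulate_study_set <- function(cfg = sim_config()) {
  .with_seed(cfg$seed, .simulate_study_set_impl(cfg))
}

.simulate_study_set_impl <- function(cfg) {
  m <- cfg$n_snps
  mafs <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "C"), c("T", "G"))
  al <- pairs[sample.int(4, m, replace = TRUE)]
  bim <- data.table::data.table(
    snp = sprintf("rs%03d", seq_len(m)), chrom = "1",
    bp = as.integer(1e6 + (seq_len(m) - 1L) * 5000L),
    a1 = vapply(al, `[`, "", 1), a2 = vapply(al, `[`, "", 2))

  c1 <- ceiling(m / 2)
  varg <- 2 * mafs * (1 - mafs)

  ## second causal variant for the linkage model: the SNP whose empirical
  ## LD r2 with c1 (in a dedicated calibration draw) is closest to target
  c2 <- NA_integer_
  if (cfg$model == "linkage") {
    gref <- simulate_genotypes(2000L, mafs, cfg$ld_decay)
    r2 <- as.vector(cor(gref[, c1], gref))^2
    r2[c1] <- NA
    c2 <- which.min(abs(r2 - cfg$linkage_r2))
  }

  ## path coefficients and theoretical scaling
  s_m <- cfg$b_zm^2 * varg[c1] + 1          # var of raw DNAm
  s_x <- cfg$b_me^2 + 1                     # var of raw expression (on std m)
  s_y <- cfg$b_et^2 + 1
  ## implied standardized effects
  bxy_mx <- if (cfg$model == "mediation") cfg$b_me / sqrt(s_x) else 0
  bxy_xy <- if (cfg$model == "mediation") cfg$b_et / sqrt(s_y) else 0
  bxy_my <- bxy_mx * bxy_xy
  ## top-SNP r2 per layer (mediation)
  r2_m <- cfg$b_zm^2 * varg[c1] / s_m
  r2_x <- r2_m * cfg$b_me^2 / s_x
  r2_y <- r2_x * cfg$b_et^2 / s_y

  ## direct (collapsed) per-allele effects used by pleiotropy/linkage so
  ## the marginal QTL signals match the mediation model's
  d_m <- cfg$b_zm / sqrt(s_m)
  d_x <- d_m * cfg$b_me / sqrt(s_x)
  d_y <- d_x * cfg$b_et / sqrt(s_y)
  if (cfg$model == "linkage" && !is.null(cfg$b_zx2)) {
    d_x <- cfg$b_zx2
    d_y <- cfg$b_zx2 * cfg$b_et / sqrt(s_y)
  }

  gen_phenos <- function(n) {
    g <- simulate_genotypes(n, mafs, cfg$ld_decay)
    mod <- cfg$model
    if (mod == "mediation") {
      mm <- .std(cfg$b_zm * g[, c1] + rnorm(n), s_m)
      xx <- .std(cfg$b_me * mm + rnorm(n), s_x)
      yy <- .std(cfg$b_et * xx + rnorm(n), s_y)
    } else if (mod == "pleiotropy") {
      vm <- d_m^2 * varg[c1]
      vx <- d_x^2 * varg[c1]
      vy <- d_y^2 * varg[c1]
      mm <- .std(d_m * g[, c1] + sqrt(max(1 - vm, 0.01)) * rnorm(n), 1)
      xx <- .std(d_x * g[, c1] + sqrt(max(1 - vx, 0.01)) * rnorm(n), 1)
      yy <- .std(d_y * g[, c1] + sqrt(max(1 - vy, 0.01)) * rnorm(n), 1)
    } else if (mod == "linkage") {
      vm <- d_m^2 * varg[c1]
      vx <- d_x^2 * varg[c2]
      vy <- d_y^2 * varg[c2]
      mm <- .std(d_m * g[, c1] + sqrt(max(1 - vm, 0.01)) * rnorm(n), 1)
      xx <- .std(d_x * g[, c2] + sqrt(max(1 - vx, 0.01)) * rnorm(n), 1)
      yy <- .std(d_y * g[, c2] + sqrt(max(1 - vy, 0.01)) * rnorm(n), 1)
    } else {
      mm <- rnorm(n); xx <- rnorm(n); yy <- rnorm(n)
    }
    list(g = g, m = mm, x = xx, y = yy)
  }

  st_m <- gen_phenos(cfg$n_mqtl)
  st_e <- gen_phenos(cfg$n_eqtl)
  st_g <- gen_phenos(cfg$n_gwas)

  ## probe layout: causal probes near the causal SNP, null probes nearby
  cbp <- bim$bp[c1]
  ann <- data.table::data.table(
    probe_id = c("cg001", "ex001"), kind = c("methylation", "expression"),
    chrom = "1", bp = as.integer(c(cbp + 500L, cbp + 50000L)),
    gene = c("", "GENE1"), strand = c("+", "+"))
  for (k in seq_len(cfg$n_null_dnam))
    ann <- rbind(ann, data.table::data.table(
      probe_id = sprintf("cg_null%d", k), kind = "methylation", chrom = "1",
      bp = as.integer(cbp + 20000L * k), gene = "", strand = "+"))
  for (k in seq_len(cfg$n_null_expr))
    ann <- rbind(ann, data.table::data.table(
      probe_id = sprintf("ex_null%d", k), kind = "expression", chrom = "1",
      bp = as.integer(cbp + 80000L * k), gene = sprintf("GENE%d", k + 1),
      strand = "-"))

  window <- 2e6
  mqtl <- list(cg001 = cis_summary(ann[probe_id == "cg001"],
                                   marginal_stats(st_m$g, st_m$m, bim),
                                   window))
  for (k in seq_len(cfg$n_null_dnam)) {
    id <- sprintf("cg_null%d", k)
    mqtl[[id]] <- cis_summary(ann[probe_id == id],
                              marginal_stats(st_m$g, rnorm(cfg$n_mqtl), bim),
                              window)
  }
  eqtl <- list(ex001 = cis_summary(ann[probe_id == "ex001"],
                                   marginal_stats(st_e$g, st_e$x, bim),
                                   window))
  for (k in seq_len(cfg$n_null_expr)) {
    id <- sprintf("ex_null%d", k)
    eqtl[[id]] <- cis_summary(ann[probe_id == id],
                              marginal_stats(st_e$g, rnorm(cfg$n_eqtl), bim),
                              window)
  }

  if (isTRUE(cfg$disease)) {
    thr <- qnorm(1 - cfg$prevalence)
    case <- as.integer(st_g$y > thr)
    gwas <- .marginal_logistic(st_g$g, case, bim)
  } else {
    gwas <- marginal_stats(st_g$g, st_g$y, bim)
  }

  panel <- ld_panel(simulate_genotypes(cfg$n_panel, mafs, cfg$ld_decay), bim)

  truth <- structure(list(
    model = cfg$model, causal = c1, causal2 = c2,
    b_xy = list(m2t = bxy_mx, m2trait = bxy_my, t2trait = bxy_xy),
    r2_top = list(methylation = r2_m, expression = r2_x, trait = r2_y),
    seed = cfg$seed), class = "SimTruth")

  list(mqtl = mqtl, eqtl = eqtl, gwas = gwas, panel = panel,
       annotations = ann, truth = truth, bim = bim)
}

#' Write a simulated study set to disk in the package's exchange formats
#'
#' Emits `mqtl.txt` and `eqtl.txt` (flat QTL format), `gwas.ma`,
#' `panel.bed/.bim/.fam`, `probes.txt` (annotation) and `truth.txt`
#' (flat key-value manifest).
#'
#' @param sim result of [simulate_study_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_files <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_qtl_flat(sim$mqtl, file.path(dir, "mqtl.txt"))
  write_qtl_flat(sim$eqtl, file.path(dir, "eqtl.txt"))
  write_gwas_ma(sim$gwas, file.path(dir, "gwas.ma"))
  write_plink(sim$panel, file.path(dir, "panel"))
  ann <- sim$annotations
  data.table::fwrite(
    data.table::data.table(ProbeID = ann$probe_id, Kind = ann$kind,
                           Chr = ann$chrom, BP = ann$bp, Gene = ann$gene,
                           Strand = ann$strand),
    file.path(dir, "probes.txt"), sep = "\t", quote = FALSE)
  tr <- sim$truth
  lines <- c(
    paste0("model=", tr$model),
    paste0("causal_snp=", sim$bim$snp[tr$causal]),
    paste0("causal_snp2=",
           if (is.na(tr$causal2)) "NA" else sim$bim$snp[tr$causal2]),
    paste0("b_xy_m2t=", format(tr$b_xy$m2t, digits = 15)),
    paste0("b_xy_m2trait=", format(tr$b_xy$m2trait, digits = 15)),
    paste0("b_xy_t2trait=", format(tr$b_xy$t2trait, digits = 15)),
    paste0("r2_methylation=", format(tr$r2_top$methylation, digits = 15)),
    paste0("r2_expression=", format(tr$r2_top$expression, digits = 15)),
    paste0("r2_trait=", format(tr$r2_top$trait, digits = 15)),
    paste0("seed=", tr$seed))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}

#' Deterministic small fixture tree for golden tests
#'
#' A mediation-model study set (30 SNPs, 4 probes) written in every
#' exchange format, plus a toy chromatin-state BED track and collapse
#' map covering the locus. Two calls with the same seed produce
#' byte-identical trees.
#'
#' @param dir output directory.
#' @param seed integer seed (default 1).
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(dir, seed = 1L) {
  ## sizes give expected instrument z of ~10 (mQTL and eQTL) and ~9
  ## (GWAS), comfortably past the 5e-8 instrument threshold
  cfg <- sim_config(model = "mediation", n_mqtl = 1000L, n_eqtl = 2000L,
                    n_gwas = 8000L, n_panel = 500L, n_snps = 30L,
                    seed = seed)
  sim <- simulate_study_set(cfg)
  write_study_files(sim, dir)

  ## toy 25-state-like track collapsed to a handful of categories
  lo <- 1e6 - 5e4
  states <- data.table::data.table(
    chrom = "1",
    start = as.integer(seq(lo, by = 20000L, length.out = 20L)),
    state = rep(c("TssA", "EnhA1", "Tx", "Quies", "Het"), 4L))
  states[, end := start + 20000L]
  data.table::fwrite(states[, .(chrom, start, end, state)],
                     file.path(dir, "states.bed"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  map <- data.table::data.table(
    raw = c("TssA", "EnhA1", "EnhA2", "Tx", "Quies", "Het"),
    cat = c("TssA", "EnhA", "EnhA", "Tx", "Quies", "Het"))
  data.table::fwrite(map, file.path(dir, "collapse_map.txt"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Draw exposure/outcome summary statistics at the asymptotic level
#'
#' Fast summary-level simulator used for calibration studies: marginal
#' z-statistics are drawn directly from their asymptotic joint normal,
#' `z ~ MVN(sqrt(n) * rho, R)`, where `rho` is the vector of true
#' SNP-phenotype correlations, and converted to (beta, se) with
#' [beta_from_z()]. Exposure and outcome draws are independent, matching
#' non-overlapping studies.
#'
#' @param R LD correlation matrix of the locus.
#' @param rho_x,rho_y true SNP-phenotype correlation vectors for the
#'   exposure and outcome phenotypes.
#' @param n_x,n_y study sample sizes.
#' @param freqs effect-allele frequencies (for the beta/se scale).
#' @param bim SNP metadata table; default metadata is generated.
#' @return list `exposure`, `outcome` (summary tables).
#' @export
simulate_summary_pair <- function(R, rho_x, rho_y, n_x, n_y, freqs,
                                  bim = NULL) {
  m <- nrow(R)
  stopifnot(length(rho_x) == m, length(rho_y) == m, length(freqs) == m)
  if (is.null(bim))
    bim <- data.table::data.table(
      snp = sprintf("rs%03d", seq_len(m)), chrom = "1",
      bp = as.integer(1e6 + (seq_len(m) - 1L) * 5000L),
      a1 = "A", a2 = "G")
  L <- chol(make_psd(R) + diag(1e-10, m))
  draw <- function(rho, n) {
    z <- sqrt(n) * rho + as.vector(crossprod(L, rnorm(m)))
    est <- beta_from_z(z, freqs, n)
    logp <- pchisq(z^2, df = 1, lower.tail = FALSE, log.p = TRUE)
    data.table::data.table(
      snp = bim$snp, chrom = bim$chrom, bp = bim$bp, a1 = bim$a1,
      a2 = bim$a2, freq = freqs, b = est$beta, se = est$se,
      p = exp(logp), logp = logp, n = as.numeric(n))
  }
  list(exposure = draw(rho_x, n_x), outcome = draw(rho_y, n_y))
}
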