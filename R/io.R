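## Readers and writers for the flat summary-statistic formats.
##
## All tables are data.tables with the internal column set
##   snp, chrom, bp, a1, a2, freq, b, se, p, logp, n
## (chrom/bp may be NA for GWAS .ma input, which carries no positions).
## a1 is the effect allele. logp is the natural-log p-value; it is the
## column used for all threshold comparisons so that p < 1e-300 survives.

.ma_header <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")
.qtl_header <- c("ProbeID", "SNP", "Chr", "BP", "A1", "A2",
                 "freq", "b", "se", "p", "N")

.num <- function(x) suppressWarnings(as.numeric(x))

## Validate numeric summary fields; returns logical keep vector and
## attaches reasons. Shared by the .ma and flat-QTL readers.
.valid_rows <- function(dt) {
  ok_num <- is.finite(dt$b) & is.finite(dt$se) & is.finite(dt$freq) &
    is.finite(dt$p) & is.finite(dt$n)
  ok_rng <- ok_num & dt$se > 0 & dt$freq > 0 & dt$freq < 1 &
    dt$p > 0 & dt$p <= 1 & dt$n >= 2
  ok_rng
}

## Wald-consistency flag: |log10 p_reported - log10 p(chi2(z^2))| > 2
.p_consistency_flag <- function(b, se, logp) {
  lp <- pchisq((b / se)^2, df = 1, lower.tail = FALSE, log.p = TRUE)
  abs(logp - lp) / log(10) > 2
}

#' Read GWAS summary statistics in GCTA-COJO .ma format
#'
#' The .ma format is whitespace-delimited with the mandatory header
#' `SNP A1 A2 freq b se p N`. Effect sizes are per-allele effects of `A1`
#' in phenotype SD units (or log odds-ratios for disease traits).
#'
#' Rows with non-numeric or out-of-range fields (`se <= 0`, `freq` outside
#' (0,1), `p` outside (0,1]) are rejected; the number of rejected rows is
#' available as `attr(x, "n_rejected")` and reported via a warning.
#'
#' @param path path to a .ma file (plain text or gzip).
#' @return a `data.table` with columns `snp, chrom, bp, a1, a2, freq, b,
#'   se, p, logp, n` and attributes `n_rejected` and `p_flagged` (count of
#'   rows whose p-value disagrees with the Wald p by more than two orders
#'   of magnitude).
#' @export
read_gwas_ma <- function(path) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character")
  if (!identical(toupper(names(dt))[1:8], toupper(.ma_header))) {
    stop("not a .ma file: expected header 'SNP A1 A2 freq b se p N', got '",
         paste(names(dt), collapse = " "), "'")
  }
  data.table::setnames(dt, .ma_header)
  out <- data.table::data.table(
    snp = dt$SNP, chrom = NA_character_, bp = NA_integer_,
    a1 = toupper(dt$A1), a2 = toupper(dt$A2),
    freq = .num(dt$freq), b = .num(dt$b), se = .num(dt$se),
    p = .num(dt$p), n = .num(dt$N))
  keep <- .valid_rows(out)
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    warning(n_rej, " row(s) rejected while reading ", path)
  out <- out[keep]
  out[, logp := log(p)]
  data.table::setcolorder(out, c("snp", "chrom", "bp", "a1", "a2", "freq",
                                 "b", "se", "p", "logp", "n"))
  flag <- .p_consistency_flag(out$b, out$se, out$logp)
  data.table::setattr(out, "n_rejected", n_rej)
  data.table::setattr(out, "p_flagged", sum(flag))
  out[]
}

#' Write a SNP summary table in .ma format
#'
#' @param dt table with internal summary columns (see [read_gwas_ma()]).
#' @param path output path.
#' @export
write_gwas_ma <- function(dt, path) {
  out <- data.table::data.table(
    SNP = dt$snp, A1 = dt$a1, A2 = dt$a2,
    freq = dt$freq, b = dt$b, se = dt$se, p = dt$p, N = dt$n)
  data.table::fwrite(out, path, sep = " ", quote = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' Tab-delimited with header `ProbeID Kind Chr BP Gene Strand`; `Kind` is
#' `expression` or `methylation`, `Gene` may be empty, `Strand` is `+`,
#' `-` or `?` (unknown).
#'
#' @param path annotation file path.
#' @return `data.table` with columns `probe_id, kind, chrom, bp, gene, strand`.
#' @export
read_probe_annotation <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("ProbeID", "Kind", "Chr", "BP", "Gene", "Strand")
  if (!all(need %in% names(dt)))
    stop("probe annotation must have header 'ProbeID Kind Chr BP Gene Strand'")
  if (!all(dt$Kind %in% c("expression", "methylation")))
    stop("Kind must be 'expression' or 'methylation'")
  out <- data.table::data.table(
    probe_id = dt$ProbeID,
    kind = dt$Kind,
    chrom = dt$Chr, bp = as.integer(dt$BP),
    gene = dt$Gene,
    strand = ifelse(dt$Strand %in% c("+", "-"), dt$Strand, "?"))
  if (anyDuplicated(out$probe_id))
    stop("duplicate probe_id in annotation: ",
         out$probe_id[duplicated(out$probe_id)][1])
  out[]
}

#' Build a cis summary object
#'
#' Couples one probe's annotation row with its cis-window SNP records.
#'
#' @param probe single-row probe annotation (list or 1-row data.table).
#' @param records SNP summary table on the probe's chromosome.
#' @param window_bp recorded cis half-window in base pairs.
#' @return object of class `CisSummary`.
#' @export
cis_summary <- function(probe, records, window_bp) {
  probe <- as.list(probe)
  if (anyDuplicated(records$snp))
    stop("duplicate snp_id in cis records for probe ", probe$probe_id)
  if (nrow(records) && !all(records$chrom == probe$chrom))
    stop("cis records off-chromosome for probe ", probe$probe_id)
  structure(list(probe = probe, records = records, window_bp = window_bp),
            class = "CisSummary")
}

#' @export
print.CisSummary <- function(x, ...) {
  cat(sprintf("CisSummary %s (%s) chr%s:%d  %d SNPs, window %g kb\n",
              x$probe$probe_id, x$probe$kind, x$probe$chrom, x$probe$bp,
              nrow(x$records), x$window_bp / 1e3))
  invisible(x)
}

#' Read a flat cis-QTL summary file
#'
#' Tab-delimited with header `ProbeID SNP Chr BP A1 A2 freq b se p N`;
#' gzip is accepted transparently. Records are grouped by probe and
#' restricted to the cis window `|BP - probe.bp| <= window_bp` on the
#' probe's chromosome. Probes missing from `annotations` are skipped and
#' counted in `attr(x, "n_unannotated")`.
#'
#' @param path QTL file path.
#' @param annotations probe annotation table from [read_probe_annotation()].
#' @param window_bp cis half-window in base pairs (default 2 Mb).
#' @return named list of [cis_summary()] objects, keyed by probe id.
#' @export
read_qtl_flat <- function(path, annotations, window_bp = 2e6) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!identical(names(dt)[1:11], .qtl_header))
    stop("not a QTL flat file: expected header '",
         paste(.qtl_header, collapse = " "), "'")
  tab <- data.table::data.table(
    probe_id = dt$ProbeID, snp = dt$SNP, chrom = dt$Chr,
    bp = as.integer(dt$BP), a1 = toupper(dt$A1), a2 = toupper(dt$A2),
    freq = .num(dt$freq), b = .num(dt$b), se = .num(dt$se),
    p = .num(dt$p), n = .num(dt$N))
  keep <- .valid_rows(tab)
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    warning(n_rej, " row(s) rejected while reading ", path)
  tab <- tab[keep]
  tab[, logp := log(p)]

  known <- tab$probe_id %in% annotations$probe_id
  n_unann <- length(unique(tab$probe_id[!known]))
  if (n_unann > 0L)
    warning(n_unann, " probe(s) absent from annotation, skipped")
  tab <- tab[known]

  ann <- data.table::setkey(data.table::copy(annotations), probe_id)
  out <- lapply(split(tab, by = "probe_id"), function(g) {
    pr <- ann[g$probe_id[1]]
    recs <- g[chrom == pr$chrom & abs(bp - pr$bp) <= window_bp,
              .(snp, chrom, bp, a1, a2, freq, b, se, p, logp, n)]
    cis_summary(pr, recs, window_bp)
  })
  attr(out, "n_rejected") <- n_rej
  attr(out, "n_unannotated") <- n_unann
  out
}

#' Write cis summaries to the flat QTL format
#'
#' @param cis_list named list of `CisSummary` objects.
#' @param path output path.
#' @export
write_qtl_flat <- function(cis_list, path) {
  rows <- data.table::rbindlist(lapply(cis_list, function(cs) {
    if (nrow(cs$records) == 0L) return(NULL)
    data.table::data.table(
      ProbeID = cs$probe$probe_id, SNP = cs$records$snp,
      Chr = cs$records$chrom, BP = cs$records$bp,
      A1 = cs$records$a1, A2 = cs$records$a2,
      freq = cs$records$freq, b = cs$records$b, se = cs$records$se,
      p = cs$records$p, N = cs$records$n)
  }))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}
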