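## Minimal PLINK 1 bed/bim/fam support.
##
## No pre-installed R package in this stack reads PLINK bed, so the 2-bit
## SNP-major codec is implemented here. Dosages count copies of the bim A1
## allele: byte codes 00 -> 2, 10 -> 1, 11 -> 0, 01 -> missing.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

## decode lookup: for each byte value, the 4 dosages (sample order LSB first)
.bed_decode_table <- local({
  tab <- matrix(NA_real_, nrow = 256, ncol = 4)
  code2dose <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  for (byte in 0:255) {
    for (s in 0:3) {
      code <- bitwAnd(bitwShiftR(byte, 2L * s), 3L)
      tab[byte + 1L, s + 1L] <- code2dose[[as.character(code)]]
    }
  }
  tab
})

#' Construct an LD reference panel object
#'
#' @param geno numeric matrix, samples x SNPs, dosages in \{0,1,2\} with NA
#'   allowed; columns named by SNP id.
#' @param bim `data.table` with columns `snp, chrom, bp, a1, a2` in column
#'   order matching `geno`.
#' @param fam optional `data.table` of sample ids.
#' @param max_missing per-SNP missingness ceiling applied at construction
#'   (default 0.05); offending SNPs are dropped with a warning.
#' @return object of class `LdPanel`.
#' @export
ld_panel <- function(geno, bim, fam = NULL, max_missing = 0.05) {
  stopifnot(ncol(geno) == nrow(bim))
  colnames(geno) <- bim$snp
  miss <- colMeans(is.na(geno))
  if (any(miss > max_missing)) {
    bad <- which(miss > max_missing)
    warning(length(bad), " SNP(s) dropped for missingness > ", max_missing)
    geno <- geno[, -bad, drop = FALSE]
    bim <- bim[-bad]
  }
  if (is.null(fam))
    fam <- data.table::data.table(iid = paste0("I", seq_len(nrow(geno))))
  structure(list(geno = geno, bim = bim, fam = fam,
                 n = nrow(geno), m = ncol(geno)),
            class = "LdPanel")
}

#' @export
print.LdPanel <- function(x, ...) {
  cat(sprintf("LdPanel: %d samples x %d SNPs\n", x$n, x$m))
  invisible(x)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim`, `.fam` must exist.
#' @param max_missing see [ld_panel()].
#' @return an `LdPanel`.
#' @export
read_plink <- function(prefix, max_missing = 0.05) {
  bim <- data.table::fread(paste0(prefix, ".bim"), header = FALSE,
                           colClasses = list(character = c(1, 2, 5, 6)))
  data.table::setnames(bim, c("chrom", "snp", "cm", "bp", "a1", "a2"))
  bim <- bim[, .(snp, chrom, bp = as.integer(bp), a1, a2)]
  fam <- data.table::fread(paste0(prefix, ".fam"), header = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bpl <- ceiling(n / 4)

  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, .bed_magic))
    stop("not a SNP-major PLINK bed v1.00 file: ", prefix, ".bed")
  raw <- readBin(con, "raw", bpl * m)
  if (length(raw) < bpl * m)
    stop("truncated bed file: ", prefix, ".bed")

  idx <- as.integer(raw) + 1L
  ## decode all bytes at once: (bpl*m) x 4, then reshape per SNP
  dec <- .bed_decode_table[idx, , drop = FALSE]
  geno <- matrix(t(dec), nrow = 4 * bpl)[seq_len(n), , drop = FALSE]
  dim(geno) <- c(n, m)
  ld_panel(geno, bim, fam = data.table::data.table(iid = as.character(fam[[2]])),
           max_missing = max_missing)
}

#' Write an LD panel as PLINK bed/bim/fam
#'
#' @param panel an `LdPanel`.
#' @param prefix output path prefix.
#' @export
write_plink <- function(panel, prefix) {
  bim <- data.table::data.table(
    chrom = panel$bim$chrom, snp = panel$bim$snp, cm = 0,
    bp = panel$bim$bp, a1 = panel$bim$a1, a2 = panel$bim$a2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t",
                     col.names = FALSE, quote = FALSE)
  fam <- data.table::data.table(
    fid = panel$fam$iid, iid = panel$fam$iid, pat = 0, mat = 0,
    sex = 0, phe = -9)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t",
                     col.names = FALSE, quote = FALSE)

  n <- panel$n
  bpl <- ceiling(n / 4)
  dose2code <- function(g) {
    code <- integer(length(g))            # 0 = hom a1 (dose 2)
    code[is.na(g)] <- 1L
    code[!is.na(g) & g == 1] <- 2L
    code[!is.na(g) & g == 0] <- 3L
    code
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  pad <- 4 * bpl - n
  for (j in seq_len(panel$m)) {
    code <- c(dose2code(panel$geno[, j]), rep(0L, pad))
    quads <- matrix(code, nrow = 4)
    bytes <- as.raw(quads[1, ] + bitwShiftL(quads[2, ], 2) +
                    bitwShiftL(quads[3, ], 4) + bitwShiftL(quads[4, ], 6))
    writeBin(bytes, con)
  }
  invisible(prefix)
}

#' Pairwise LD correlation matrix from a reference panel
#'
#' Pearson correlation of dosages with pairwise-complete handling of
#' missing genotypes. `flip` reverses the sign of selected columns so the
#' matrix is expressed on harmonized effect alleles.
#'
#' @param panel an `LdPanel`.
#' @param snp_ids ordered SNP ids; all must be in the panel.
#' @param flip optional logical vector (same length) marking SNPs whose
#'   panel A1 is the harmonized other allele.
#' @return symmetric correlation matrix with unit diagonal, dimnames set
#'   to `snp_ids`.
#' @export
ld_matrix <- function(panel, snp_ids, flip = NULL) {
  j <- match(snp_ids, colnames(panel$geno))
  if (anyNA(j))
    stop("SNP(s) not in panel: ", paste(snp_ids[is.na(j)], collapse = ", "))
  g <- panel$geno[, j, drop = FALSE]
  sds <- apply(g, 2, sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0))
    stop("monomorphic SNP(s) in panel: ",
         paste(snp_ids[!is.finite(sds) | sds == 0], collapse = ", "))
  if (!is.null(flip)) {
    stopifnot(length(flip) == length(snp_ids))
    g[, flip] <- 2 - g[, flip, drop = FALSE]
  }
  R <- stats::cor(g, use = "pairwise.complete.obs")
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalues below `-tol * max(eigenvalue)` trigger clipping at zero;
#' the clipped magnitude is reported via attribute `psd_clip`.
#'
#' @param R symmetric matrix.
#' @param tol relative clipping threshold (default 1e-8).
#' @return PSD-repaired matrix with attribute `psd_clip` (total clipped
#'   eigenvalue mass, 0 when nothing was clipped).
#' @export
make_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  lam <- e$values
  floor_ <- -tol * max(abs(lam))
  if (min(lam) >= floor_ && min(lam) >= 0) {
    attr(R, "psd_clip") <- 0
    return(R)
  }
  clip <- sum(pmin(lam, 0))
  lam2 <- pmax(lam, 0)
  out <- e$vectors %*% (lam2 * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(R)
  attr(out, "psd_clip") <- abs(clip)
  out
}

#' Panel allele frequencies (frequency of the bim A1 allele)
#'
#' @param panel an `LdPanel`.
#' @param snp_ids SNP ids to extract.
#' @return named numeric vector.
#' @export
panel_freq <- function(panel, snp_ids) {
  j <- match(snp_ids, colnames(panel$geno))
  if (anyNA(j))
    stop("SNP(s) not in panel: ", paste(snp_ids[is.na(j)], collapse = ", "))
  setNames(colMeans(panel$geno[, j, drop = FALSE], na.rm = TRUE) / 2, snp_ids)
}
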