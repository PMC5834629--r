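test_that("beta_from_z matches the closed form and the z identity", {
  r <- beta_from_z(0, 0.5, 1000)
  expect_equal(r$beta, 0)
  expect_equal(r$se, 1 / sqrt(500))

  # frozen 50-digit arithmetic oracle for z = 5, freq = 0.2, n = 10000
  r2 <- beta_from_z(5, 0.2, 10000)
  expect_equal(r2$se, 0.017655613788661216911, tolerance = 1e-13)
  expect_equal(r2$beta, 0.088278068943306084556, tolerance = 1e-13)

  set.seed(1)
  z <- rnorm(50, sd = 4)
  f <- runif(50, 0.01, 0.99)
  n <- sample(100:100000, 50)
  r3 <- beta_from_z(z, f, n)
  expect_equal(r3$beta / r3$se, z)

  expect_error(beta_from_z(1, 1.2, 100), "freq")
})

test_that("meta_fixed matches a weighted-least-squares oracle", {
  a <- snp_tab("rs1", b = 0.1, se = 0.05, n = 600)
  b <- snp_tab("rs1", b = 0.3, se = 0.05, n = 1400)
  m <- meta_fixed(a, b)
  expect_equal(m$b, 0.2)
  expect_equal(m$se, 0.05 / sqrt(2))
  expect_equal(m$n, 2000)

  # SNP present in one cohort only is dropped
  a2 <- snp_tab(c("rs1", "rs2"), b = c(0.1, 0.5), se = 0.05)
  expect_identical(meta_fixed(a2, b)$snp, "rs1")

  # random inputs vs lm(weights = 1/se^2) intercept-only WLS
  set.seed(2)
  for (i in 1:10) {
    x <- snp_tab("rs1", b = rnorm(1), se = runif(1, 0.01, 0.5), n = 500)
    y <- snp_tab("rs1", b = rnorm(1), se = runif(1, 0.01, 0.5), n = 500)
    m <- meta_fixed(x, y)
    fit <- lm(c(x$b, y$b) ~ 1, weights = c(1 / x$se^2, 1 / y$se^2))
    expect_equal(m$b, unname(coef(fit)[1]), tolerance = 1e-10)
  }
})

test_that("meta_fixed variance never exceeds the smaller input variance", {
  set.seed(3)
  for (i in 1:20) {
    x <- snp_tab("rs1", b = rnorm(1), se = runif(1, 0.01, 1))
    y <- snp_tab("rs1", b = rnorm(1), se = runif(1, 0.01, 1))
    expect_lte(meta_fixed(x, y)$se, min(x$se, y$se))
  }
})

test_that("filter_probes applies MAF, instrument and MHC rules", {
  mk <- function(id, chrom, bp, ps, freqs = rep(0.3, length(ps))) {
    recs <- snp_tab(sprintf("%s_rs%d", id, seq_along(ps)),
                    b = rep(0.1, length(ps)), se = 0.05,
                    freq = freqs, chrom = chrom, p = ps)
    cis_summary(toy_probe(id, chrom = chrom, bp = bp), recs, 2e6)
  }
  cis <- list(
    ok = mk("ok", "1", 1e6, c(1e-9, 0.5)),
    weak = mk("weak", "1", 1e6, c(1e-7, 0.5)),          # best p > 5e-8
    mhc = mk("mhc", "6", 30e6, c(1e-9, 0.5)),
    rare = mk("rare", "1", 1e6, 1e-9, freqs = 0.005))   # MAF kills instrument
  out <- filter_probes(cis)
  expect_named(out, "ok")
  rep <- attr(out, "report")
  expect_equal(unname(rep["no_instrument"]), 2L)  # weak + rare
  expect_equal(unname(rep["mhc"]), 1L)
  expect_equal(unname(rep["snp_maf"]), 1L)

  # enumeration oracle on a random synthetic set
  set.seed(4)
  cis2 <- list()
  expected <- character(0)
  for (k in 1:30) {
    id <- sprintf("p%02d", k)
    ps <- 10^-runif(3, 0, 12)
    chrom <- sample(c("1", "6"), 1)
    bp <- sample(c(1e6, 30e6), 1)
    cis2[[id]] <- mk(id, chrom, bp, ps)
    in_mhc <- chrom == "6" && bp >= 25e6 && bp <= 34e6
    if (min(ps) < 5e-8 && !in_mhc) expected <- c(expected, id)
  }
  expect_setequal(names(filter_probes(cis2)), expected)
})

test_that("ld_matrix agrees with a naive two-pass oracle", {
  set.seed(5)
  g <- simulate_genotypes(300, runif(20, 0.1, 0.5), ld_decay = 0.7)
  g[sample(length(g), 100)] <- NA  # sprinkle missingness
  panel <- suppressWarnings(toy_panel(g))
  ids <- panel$bim$snp
  R <- ld_matrix(panel, ids)
  expect_equal(diag(R), setNames(rep(1, length(ids)), ids))
  expect_equal(R, t(R))
  expect_true(all(R >= -1 & R <= 1))

  naive <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (pair in list(c(1, 2), c(3, 17), c(5, 20))) {
    expect_equal(R[pair[1], pair[2]],
                 naive(panel$geno[, pair[1]], panel$geno[, pair[2]]),
                 tolerance = 1e-10)
  }

  # duplicated genotype column gives off-diagonal 1
  g2 <- cbind(g[, 1], g[, 1])
  p2 <- suppressWarnings(toy_panel(g2, snp = c("a", "b")))
  expect_equal(ld_matrix(p2, c("a", "b"))["a", "b"], 1)

  # monomorphic SNP errors by name
  g3 <- cbind(g[, 1], rep(2, 300))
  p3 <- toy_panel(g3, snp = c("a", "mono"))
  expect_error(ld_matrix(p3, c("a", "mono")), "mono")
})

test_that("make_psd clips negative eigenvalues and logs the amount", {
  R <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3)  # indefinite
  expect_lt(min(eigen(R)$values), 0)
  R2 <- make_psd(R)
  expect_gte(min(eigen(R2)$values), -1e-12)
  expect_gt(attr(R2, "psd_clip"), 0)
  # PSD input untouched
  R3 <- make_psd(diag(3))
  expect_equal(attr(R3, "psd_clip"), 0)
})

test_that("qtl_variance_explained matches formula and simulation", {
  expect_equal(qtl_variance_explained(0, 100), 0)
  expect_equal(qtl_variance_explained(10, 1000), 100 / 1098)
  expect_error(qtl_variance_explained(1, 2), "n must be")
  # monotone in |z|
  z <- seq(0, 20, by = 0.5)
  expect_true(all(diff(qtl_variance_explained(z, 500)) > 0))

  # regression simulation oracle: r2 from a real regression of phenotype
  # on dosage matches the z-derived value
  set.seed(6)
  n <- 2000
  err <- replicate(200, {
    g <- rbinom(n, 2, 0.3)
    y <- 0.15 * g + rnorm(n)
    fit <- summary(lm(y ~ g))
    z <- coef(fit)["g", "t value"]
    abs(qtl_variance_explained(z, n) - fit$r.squared)
  })
  expect_lt(mean(err), 0.005)
})
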