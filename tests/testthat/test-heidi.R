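test_that("select_heidi_snps prunes LD and truncates by significance", {
  set.seed(10)
  m <- 40
  g <- simulate_genotypes(1500, rep(0.3, m), ld_decay = 0.95)
  panel <- toy_panel(g)
  ids <- panel$bim$snp
  # strong instrument in the middle; p decays with distance
  inst <- ids[20]
  ps <- 10^-(20 - abs(seq_len(m) - 20))
  recs <- snp_tab(ids, b = 1, se = 1, p = pmin(ps, 0.999),
                  bp = panel$bim$bp)
  cis <- cis_summary(toy_probe(), recs, 2e6)
  sel <- select_heidi_snps(cis, panel, inst)
  expect_identical(sel[1], inst)
  expect_lte(length(sel), 21L)
  R <- ld_matrix(panel, c(inst, setdiff(sel, inst)))
  r2 <- R[1, -1]^2
  expect_true(all(r2 >= 0.05 & r2 <= 0.9))

  # sort-and-slice oracle: candidates ranked by p, capped at max_snps
  Rall <- ld_matrix(panel, c(inst, setdiff(ids, inst)))
  r2all <- setNames(Rall[1, -1]^2, setdiff(ids, inst))
  elig <- recs[snp != inst & p < 1.57e-3]
  elig <- elig[r2all[snp] >= 0.05 & r2all[snp] <= 0.9]
  oracle <- elig[order(logp, bp, snp)][seq_len(min(.N, 20L)), snp]
  expect_identical(setdiff(sel, inst), oracle)
})

test_that("heidi_cov collapses cross terms under independence", {
  # 3 SNPs (instrument + 2), R = I: V_12 = var(b_xy(0))
  ex <- snp_tab(c("s0", "s1", "s2"), b = c(0.5, 0.4, 0.45), se = 0.05)
  oy <- snp_tab(c("s0", "s1", "s2"), b = c(0.2, 0.15, 0.18), se = 0.03)
  ctx <- heidi_cov(ex, oy, diag(3))
  var0 <- (0.03 / 0.5)^2 + 0.2^2 * 0.05^2 / 0.5^4
  expect_equal(ctx$V[1, 2], var0)
  expect_equal(ctx$V, t(ctx$V))
  expect_true(all(diag(ctx$V) > 0))
  expect_equal(ctx$d, c(0.15 / 0.4 - 0.2 / 0.5, 0.18 / 0.45 - 0.2 / 0.5))

  # weak instrument guard
  ex_weak <- snp_tab(c("s0", "s1"), b = c(0.5, 0.01), se = 0.05)
  oy2 <- snp_tab(c("s0", "s1"), b = c(0.2, 0.1), se = 0.03)
  expect_error(heidi_cov(ex_weak, oy2, diag(2)), "weak instrument")
})

test_that("heidi_cov V matches Monte-Carlo covariance of d", {
  # generating model: pleiotropy with true effects, draws of summary
  # stats from the exact MVN; empirical cov(d) must match the V computed
  # at the true parameter values within MC error
  set.seed(11)
  m <- 4
  R <- ar1_R(m, 0.6)
  L <- chol(R)
  bx <- c(0.5, 0.4, 0.35, 0.3)
  sx <- rep(0.01, m)   # small SEs keep the first-order expansion tight
  bxy <- 0.4
  by <- bxy * bx
  sy <- rep(0.008, m)
  nrep <- 1e5
  Zx <- matrix(rnorm(nrep * m), nrep) %*% L
  Zy <- matrix(rnorm(nrep * m), nrep) %*% L
  BX <- sweep(sweep(Zx, 2, sx, "*"), 2, bx, "+")
  BY <- sweep(sweep(Zy, 2, sy, "*"), 2, by, "+")
  Dhat <- BY[, -1] / BX[, -1] - BY[, 1] / BX[, 1]
  emp <- cov(Dhat)

  ex <- snp_tab(sprintf("s%d", 1:m), b = bx, se = sx)
  oy <- snp_tab(sprintf("s%d", 1:m), b = by, se = sy)
  V <- heidi_cov(ex, oy, R)$V
  # MC standard error of a covariance entry ~ sqrt((V_ii V_jj + V_ij^2)/n)
  for (i in 1:(m - 1)) for (j in 1:(m - 1)) {
    mc_se <- sqrt((V[i, i] * V[j, j] + V[i, j]^2) / nrep)
    expect_lt(abs(emp[i, j] - V[i, j]), 3 * mc_se)
  }
})

test_that("heidi_test handles degenerate and diagonal cases", {
  ctx <- structure(list(d = rep(0, 5), V = diag(5), weights = rep(1, 5)),
                   class = "HeidiContext")
  expect_equal(heidi_test(ctx)$p_heidi, 1)

  # V diagonal, m = 5, t at the chi2_5 95th percentile -> p = 0.05
  t95 <- qchisq(0.95, df = 5)
  d <- sqrt(rep(t95 / 5, 5))
  ctx2 <- structure(list(d = d, V = diag(5), weights = rep(1, 5)),
                    class = "HeidiContext")
  expect_equal(heidi_test(ctx2)$p_heidi, 0.05, tolerance = 1e-10)

  ctx3 <- structure(list(d = c(1, 1), V = diag(2), weights = c(1, 1)),
                    class = "HeidiContext")
  expect_true(is.na(heidi_test(ctx3, min_snps = 3)$p_heidi))
})

test_that("heidi p is invariant to common rescaling of exposure effects", {
  set.seed(12)
  m <- 5
  R <- ar1_R(m, 0.5)
  ex <- snp_tab(sprintf("s%d", 1:m), b = runif(m, 0.3, 0.6), se = 0.02)
  oy <- snp_tab(sprintf("s%d", 1:m), b = runif(m, 0.1, 0.2), se = 0.02)
  p1 <- heidi_test(heidi_cov(ex, oy, R))$p_heidi
  ex2 <- data.table::copy(ex)[, `:=`(b = b * 3, se = se * 3)]
  p2 <- heidi_test(heidi_cov(ex2, oy, R))$p_heidi
  expect_equal(p2, p1, tolerance = 1e-12)
})

test_that("heidi is calibrated in the strong-instrument regime", {
  # With secondary instruments far from the eligibility floor the
  # first-order delta approximation is accurate and the null rejection
  # rate is nominal (cf. the acceptance calibration at a realistic mQTL
  # sample size, where weak secondaries inflate it mildly).
  m <- 20
  R <- ar1_R(m, 0.2^(1 / 8))
  c1 <- 10
  set.seed(41)
  nrep <- 1000
  ps <- replicate(nrep, {
    d <- heidi_sim_draw(R, c1, c1, r2x = 0.095, r2y = 0.001,
                        n_x = 20000, n_y = 50000)
    heidi_p_from_draw(d, R)
  })
  rej <- sum(ps < 0.01, na.rm = TRUE)
  ci <- qbinom(c(0.025, 0.975), sum(!is.na(ps)), 0.01)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})
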