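make_bed <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_bed_states converts coordinates and collapses labels", {
  bed <- make_bed(c("chr1\t0\t200\tTssA", "chr1\t200\t400\tEnhA1"))
  map <- c(TssA = "TssA", EnhA1 = "EnhA", EnhA2 = "EnhA")
  ann <- read_bed_states(bed, map)
  probes <- data.table::data.table(probe_id = c("p1", "p2", "p3"),
                                   chrom = "1", bp = c(1L, 250L, 999L))
  got <- assign_category(probes, ann)
  expect_equal(unname(got), c("TssA", "EnhA", "unannotated"))

  # overlapping raw intervals of one category are merged
  bed2 <- make_bed(c("chr1\t0\t300\tEnhA1", "chr1\t200\t500\tEnhA2"))
  ann2 <- read_bed_states(bed2, map)
  gr <- ann2$tracks[[1]]
  expect_equal(length(gr[gr$category == "EnhA"]), 1L)

  bed3 <- make_bed("chr1\t0\t100\tMystery")
  expect_error(read_bed_states(bed3, map), "Mystery")
})

test_that("assign_category matches a linear-scan oracle on random fixtures", {
  set.seed(26)
  for (rep in 1:5) {
    n_iv <- 15
    starts <- sort(sample.int(5000, n_iv))
    ends <- starts + sample.int(300, n_iv)
    labs <- sample(c("A", "B", "C"), n_iv, TRUE)
    bed <- make_bed(sprintf("chr2\t%d\t%d\t%s", starts, ends, labs))
    ann <- read_bed_states(bed, NULL)
    pos <- sample.int(6000, 50)
    probes <- data.table::data.table(probe_id = sprintf("p%02d", 1:50),
                                     chrom = "2", bp = pos)
    got <- assign_category(probes, ann)
    # oracle: scan merged per-category intervals; resolve overlaps toward
    # the interval with the smallest start
    oracle <- vapply(pos, function(x) {
      hit <- which(starts < x & x <= ends)  # bed half-open, 1-based query
      if (length(hit) == 0) return("unannotated")
      # merged intervals: find category whose merged span covers x with
      # the smallest merged start
      cover <- vapply(c("A", "B", "C"), function(lb) {
        iv <- which(labs == lb)
        any(starts[iv] < x & x <= ends[iv])
      }, logical(1))
      if (!any(cover)) return("unannotated")
      cats <- names(cover)[cover]
      # emulate the first-by-start rule over merged category intervals
      best_start <- vapply(cats, function(lb) {
        iv <- which(labs == lb & starts < x & x <= ends)
        min(starts[iv])
      }, 0)
      cats[which.min(best_start)]
    }, "")
    mism <- which(got != oracle)
    # merged intervals can extend a category's start leftward past another
    # category's interval; only compare positions with a unique cover
    simple <- vapply(pos, function(x)
      sum(starts < x & x <= ends) <= 1, logical(1))
    expect_equal(unname(got[simple]), oracle[simple])
  }
})

test_that("variance_matched_sample matches cardinality and seed contract", {
  set.seed(27)
  uni <- data.table::data.table(probe_id = sprintf("p%04d", 1:1000),
                                variance = rexp(1000))
  targets <- sample(uni$probe_id, 120)
  s1 <- variance_matched_sample(uni, targets, rng_seed = 99)
  s2 <- variance_matched_sample(uni, targets, rng_seed = 99)
  s3 <- variance_matched_sample(uni, targets, rng_seed = 100)
  expect_length(s1, length(targets))
  expect_identical(as.character(s1), as.character(s2))
  expect_false(identical(as.character(s1), as.character(s3)))
  expect_false(any(s1 == targets))  # a target never draws itself

  expect_error(variance_matched_sample(uni, "nope", rng_seed = 1),
               "missing from universe")
})

test_that("matched samples reproduce the target variance distribution", {
  set.seed(28)
  uni <- data.table::data.table(probe_id = sprintf("p%04d", 1:2000),
                                variance = rgamma(2000, 0.5))
  # variance-biased target set: without matching, KS would reject
  targets <- uni[order(-variance)][1:600, probe_id][sample.int(600, 150)]
  v <- setNames(uni$variance, uni$probe_id)
  ok <- replicate(200, {
    smp <- variance_matched_sample(uni, targets, rng_seed = NULL)
    suppressWarnings(ks.test(v[targets], v[smp])$p.value) > 0.01
  })
  expect_gte(mean(ok), 0.95)
})

test_that("enrichment_test: proportions sum to 1, folds behave", {
  set.seed(29)
  n <- 1500
  uni <- data.table::data.table(probe_id = sprintf("p%04d", 1:n),
                                variance = runif(n))
  cats <- setNames(sample(c("EnhA", "TssA", "Quies"), n, TRUE,
                          prob = c(0.3, 0.2, 0.5)), uni$probe_id)

  # targets concentrated in EnhA -> fold ~ 1/0.3 for EnhA
  targets <- sample(names(cats)[cats == "EnhA"], 100)
  res <- enrichment_test(targets, uni, cats, n_fold_reps = 200,
                         n_se_reps = 60, rng_seed = 5)
  expect_equal(sum(res$observed), 1)
  enh <- res[category == "EnhA"]
  expect_equal(enh$observed, 1)
  expect_equal(enh$fold, 1 / enh$null_mean)
  expect_gt(enh$fold, 2)
  expect_gt(enh$z, 3)

  # byte-identical under a fixed seed
  res2 <- enrichment_test(targets, uni, cats, n_fold_reps = 200,
                          n_se_reps = 60, rng_seed = 5)
  expect_identical(res, res2)

  # fold for a category is invariant to relabeling other categories
  cats_relab <- cats
  cats_relab[cats_relab == "Quies"] <- "Het"
  res3 <- enrichment_test(targets, uni, cats_relab, n_fold_reps = 200,
                          n_se_reps = 60, rng_seed = 5)
  expect_equal(res3[category == "EnhA", fold], enh$fold)
})

test_that("doubling replicates moves null_mean by < 3 MC standard errors", {
  set.seed(30)
  n <- 800
  uni <- data.table::data.table(probe_id = sprintf("p%03d", 1:n),
                                variance = runif(n))
  cats <- setNames(rep(c("A", "B"), n / 2), uni$probe_id)
  targets <- sample(uni$probe_id, 80)
  r1 <- enrichment_test(targets, uni, cats, n_fold_reps = 150,
                        n_se_reps = 50, rng_seed = 7)
  r2 <- enrichment_test(targets, uni, cats, n_fold_reps = 300,
                        n_se_reps = 50, rng_seed = 8)
  # per-replicate proportion SD ~ sqrt(p(1-p)/|targets|)
  for (k in seq_len(nrow(r1))) {
    p <- r1$null_mean[k]
    mc_se <- sqrt(p * (1 - p) / 80) / sqrt(150)
    expect_lt(abs(r1$null_mean[k] - r2$null_mean[k]), 3 * sqrt(2) * mc_se)
  }
})
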