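test_that("dominant grouping pools Val carriers against Met homozygotes", {
  g <- rep(c("Met/Met", "Met/Val", "Val/Val"), c(129L, 224L, 77L))
  grp <- dominantGrouping(g)
  expect_equal(grp$n_val, 301L)
  expect_equal(grp$n_met, 129L)
  grp <- dominantGrouping(rep(c("Met/Met", "Met/Val", "Val/Val"),
                              c(23L, 37L, 10L)))
  expect_equal(grp$n_val, 47L)
  expect_equal(grp$n_met, 23L)
  expect_error(dominantGrouping(c(NA_character_, NA_character_)),
               "no genotyped")
  # cohort method partitions the genotyped twins
  co <- genCohort(simulationConfig(nPairsTotal = 30L, seed = 3L))$cohort
  grp <- dominantGrouping(co)
  expect_equal(sort(c(grp$val_plus, grp$met_plus)),
               sort(twinIds(co)[!is.na(genotypeCalls(co))]))
})

test_that("the HWE chi-square matches hand-computed expectations", {
  h <- hweChiSquare(c(25, 50, 25))
  expect_equal(h$chi2, 0)
  expect_equal(h$allele_freq_p, 0.5)
  h <- hweChiSquare(c(129, 224, 77))
  expect_equal(h$chi2, 1.413, tolerance = 1e-3)
  expect_equal(h$expected, c(135.07, 211.86, 83.07), tolerance = 1e-4)
  expect_equal(sum(h$expected), 430)
  expect_equal(h$df, 1L)
  expect_equal(hweChiSquare(c(129, 224, 77), labelDf2 = TRUE)$df, 2L)
  # monomorphic convention
  expect_equal(hweChiSquare(c(0, 0, 50))$chi2, 0)
  expect_error(hweChiSquare(c(-1, 2, 3)), "non-negative")
  # label/allele symmetry: reversing the homozygote order preserves chi2
  set.seed(4)
  for (i in 1:20) {
    cnt <- rmultinom(1, 300, c(0.3, 0.5, 0.2))[, 1]
    expect_equal(hweChiSquare(cnt)$chi2, hweChiSquare(rev(cnt))$chi2)
    expect_equal(sum(hweChiSquare(cnt)$expected), sum(cnt))
  }
})

test_that("the Mann-Whitney U counts dominances with half tie credit", {
  expect_equal(mannWhitneyU(c(3, 4), c(1, 2))$U, 4)
  expect_equal(mannWhitneyU(c(1, 2), c(3, 4))$U, 0)
  expect_equal(mannWhitneyU(c(1, 2, 3), c(1, 2, 3))$U, 4.5)
  # brute-force dominance count over random tied integer samples
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:6, 7, replace = TRUE)
    y <- sample(1:6, 5, replace = TRUE)
    brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(mannWhitneyU(x, y)$U, brute)
  }
})

test_that("Mann-Whitney p-values agree with the reference implementation", {
  set.seed(6)
  # small samples, no ties: exact enumeration vs wilcox.test exact
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mannWhitneyU(x, y)$p,
                 wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # large samples: tie- and continuity-corrected normal approximation
  x <- round(rnorm(60, sd = 3)); y <- round(rnorm(55, sd = 3))
  mw <- mannWhitneyU(x, y)
  wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$method, "normal_approx")
  expect_equal(mw$p, wt$p.value)
  expect_equal(mw$U, unname(wt$statistic))
})

test_that("t tests handle the pooled, Welch and degenerate cases", {
  x <- c(2, 2, 2); y <- c(2, 2, 2, 2)
  tt <- twoSampleT(x, y)
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  expect_error(twoSampleT(c(1, 1), c(2, 2)), "zero variance")
  set.seed(8)
  tt <- twoSampleT(rnorm(200, 1), rnorm(200, 0))
  expect_lt(tt$p, 0.001)
  expect_equal(tt$df, 398)
  # Welch df never exceeds the pooled df
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    expect_lte(twoSampleT(x, y, pooled = FALSE)$df,
               twoSampleT(x, y, pooled = TRUE)$df)
  }
})

test_that("Cohen's d recovers planted shifts with a sane noncentral-t CI", {
  set.seed(9)
  x <- rnorm(300); y <- rnorm(300)
  d0 <- cohensD(x, y)
  expect_lt(d0$ci_low, 0); expect_gt(d0$ci_high, 0)
  d <- cohensD(rnorm(200, 0.5), rnorm(200, 0))
  expect_lt(abs(d$d - 0.5), 0.15)
  expect_true(d$ci_low <= d$d && d$d <= d$ci_high)
  # CI width shrinks with n
  widths <- vapply(c(20, 80, 320), function(n) {
    set.seed(n)
    ci <- cohensD(rnorm(n, 0.3), rnorm(n))
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("the rank-biserial transform is the dominance statistic", {
  expect_equal(rankBiserial(129 * 301 / 2, 129, 301), 0)
  expect_error(rankBiserial(-1, 5, 5), "U must lie")
  # equals (favorable - unfavorable) / (n1 n2) by pair enumeration
  set.seed(10)
  for (i in 1:20) {
    x <- sample(1:5, 6, replace = TRUE)
    y <- sample(1:5, 4, replace = TRUE)
    U <- mannWhitneyU(x, y)$U
    fav <- sum(outer(x, y, ">")); unf <- sum(outer(x, y, "<"))
    expect_equal(rankBiserial(U, 6, 4), (fav - unf) / 24)
  }
})

test_that("the rank-biserial CI is a U-scale normal approximation", {
  ci <- rankBiserialCi(100 * 100 / 2, 100, 100)
  expect_equal(ci$ci_low, -ci$ci_high)
  ci <- rankBiserialCi(22341.5, 129, 301)
  expect_lt(abs(ci$ci_low - 0.0315), 1e-3)
  expect_lt(abs(ci$ci_high - 0.2700), 1e-3)
  # the interval always contains the point estimate, and stays in [-1, 1]
  set.seed(11)
  for (i in 1:20) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    U <- runif(1, 0, n1 * n2)
    r <- rankBiserial(U, n1, n2)
    ci <- rankBiserialCi(U, n1, n2)
    expect_true(ci$ci_low <= r && r <= ci$ci_high)
    expect_gte(ci$ci_low, -1); expect_lte(ci$ci_high, 1)
  }
})

test_that("Bonferroni adjustment is the capped multiple of p", {
  expect_equal(bonferroniAdjust(0, 5), 0)
  expect_equal(bonferroniAdjust(0.7, 2), 1)
  expect_error(bonferroniAdjust(1.2, 2), "p must")
  expect_error(bonferroniAdjust(0.1, 0), "positive integer")
  # monotone in p and in m, never above 1
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroniAdjust(p, 3)) >= 0))
  expect_true(all(bonferroniAdjust(p, 7) >= bonferroniAdjust(p, 2)))
  expect_true(all(bonferroniAdjust(p, 50) <= 1))
})

test_that("the SNP battery produces 35 catalog-ordered, deterministic rows", {
  co <- genCohort(simulationConfig(seed = 12L))$cohort
  res <- runSnpBattery(co)
  expect_equal(nrow(res), 35L)
  expect_equal(res$scale, neoScales()$scale)
  expect_true(all(res$test %in% c("student_t", "welch_t", "mann_whitney")))
  expect_equal(res$p_bonf, pmin(1, 2 * res$p))
  expect_true(all(res$effect >= res$effect_ci_low &
                  res$effect <= res$effect_ci_high))
  expect_identical(res, runSnpBattery(co))
  # an all-Met/Met cohort has an empty Val+ group
  expect_error(runSnpBattery(fixtureCohort(4L, genotype = "Met/Met")),
               "non-empty")
})

test_that("the SNP battery is calibrated when its independence assumptions hold", {
  # icc = 0: twins uncorrelated, so treating them as independent is exact
  cat35 <- neoScales()
  icc0 <- setNames(rep(0, 35L), cat35$column)
  rej <- vapply(1:30, function(s) {
    co <- genCohort(simulationConfig(nPairsTotal = 60L, iccMz = icc0,
                                     nEpiPairs = 0L,
                                     seed = 7000L + s))$cohort
    mean(runSnpBattery(co)$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  rate <- mean(rej)  # 1050 scale-level tests
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("treating correlated co-twins as independent inflates the null rate", {
  # the documented clustering caveat: with MZ co-twins sharing genotype and
  # trait ICC 0.5, the independence-based battery is liberal at the null
  rej <- vapply(1:30, function(s) {
    co <- genCohort(simulationConfig(nPairsTotal = 60L, nEpiPairs = 0L,
                                     seed = 40000L + s))$cohort
    mean(runSnpBattery(co)$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  rate <- mean(rej)
  expect_gt(rate, 0.06)
  expect_lt(rate, 0.2)
})

test_that("a planted genotype group shift is recovered by the battery", {
  gs <- list(scale = "Gregariousness", deltaInSd = 0.6)
  co <- genCohort(simulationConfig(groupShift = gs, seed = 13L))$cohort
  res <- runSnpBattery(co)
  row <- res[res$scale == "Gregariousness", ]
  expect_lt(row$p_bonf, 0.05)
  expect_gt(row$effect, 0)  # shift was added to the Met+ group
})
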