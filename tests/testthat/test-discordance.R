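test_that("pairs are oriented by methylation rank with tie exclusion", {
  meth <- matrix(10, 5, 6)
  meth[, 1:2] <- c(10, 5)      # pair 1: first twin higher everywhere
  meth[, 3:4] <- 0             # pair 2: tied at zero everywhere
  meth[, 5:6] <- c(3, 8)       # pair 3: second twin higher
  co <- fixtureCohort(3L, meth = meth)
  ori <- orientPairs(co, 1)
  expect_equal(ori$high_twin[1], "T1")
  expect_equal(ori$low_twin[1], "T2")
  expect_true(ori$excluded[2])
  expect_equal(ori$reason[2], "methylation tie")
  expect_equal(ori$high_twin[3], "T6")
})

test_that("twin classification applies the alternative-specific tie rules", {
  mkCo <- function(t1, t2)
    fixtureCohort(1L, meth = c(10, 5),
                  traits = list(Impulsiveness = c(t1, t2)))
  cl <- classifyPairs(mkCo(20, 15), 1, "Impulsiveness", "greater")
  expect_equal(cl$meth_rank, c("H", "L"))
  expect_equal(cl$trait_status, c("Higher", "NotHigher"))
  # trait ties are kept, as "not higher" under the greater alternative ...
  cl <- classifyPairs(mkCo(20, 20), 1, "Impulsiveness", "greater")
  expect_equal(cl$trait_status, c("NotHigher", "NotHigher"))
  # ... and as "not lower" under the less alternative
  cl <- classifyPairs(mkCo(20, 20), 1, "Impulsiveness", "less")
  expect_equal(cl$trait_status, c("NotLower", "NotLower"))
  cl <- classifyPairs(mkCo(15, 20), 1, "Impulsiveness", "less")
  expect_equal(cl$trait_status, c("Lower", "NotLower"))
})

test_that("contingency construction matches hand enumeration for both designs", {
  meth <- matrix(0, 5, 6)
  meth[, 1:2] <- c(10, 5)      # H twin: first; its trait is higher
  meth[, 3:4] <- c(3, 8)       # H twin: second; its trait is lower
  meth[, 5:6] <- 4             # methylation tie -> excluded
  co <- fixtureCohort(3L, meth = meth,
                      traits = list(Warmth = c(20L, 15L, 30L, 12L,
                                               22L, 25L)))
  # both-twins: rows of size 2; H row holds one Higher and one Lower twin
  cell <- buildContingency(co, 1, "Warmth", "greater",
                           pairContribution = "both_twins")
  expect_equal(cell$n_pairs_used, 2L)
  expect_equal(cell$n_pairs_excluded, 1L)
  expect_equal(c(cell$n1, cell$n2), c(2L, 2L))
  expect_equal(cell$x1, 1L)    # success = NotHigher: pair-2 H twin only
  expect_equal(cell$x2, 1L)    # mirrored in the L row
  # index-twin: pairs split by whether the first twin is the H twin
  cell <- buildContingency(co, 1, "Warmth", "greater",
                           pairContribution = "index_twin")
  expect_equal(c(cell$n1, cell$n2), c(1L, 1L))
  expect_equal(cell$x1, 0L)    # pair 1: index twin H, its trait higher
  expect_equal(cell$x2, 0L)    # pair 2: index twin L, its trait also higher
})

test_that("mirrored rows satisfy the exact count symmetry on tie-free data", {
  co <- nullEpiCohort(25L, seed = 41L)
  for (cpg in c(1L, 4L)) {
    cells <- runEpigeneticBattery(co, alternatives = "greater",
                                  pairContribution = "both_twins")
    sub <- cells[cells$cpg == cpg, ]
    tr <- traitScores(epigeneticView(co))
    idx <- pairIndex(epigeneticView(co))
    noTies <- vapply(seq_len(35L), function(j)
      all(tr[j, idx[1, ]] != tr[j, idx[2, ]]), logical(1))
    # count(H, Lower) = count(L, Higher): x2 = n1 - x1 exactly
    expect_equal(sub$x2[noTies], sub$n1[noTies] - sub$x1[noTies])
  }
})

test_that("the greater and less alternatives share the table and obey row-swap duality", {
  co <- nullEpiCohort(20L, seed = 43L)
  cg <- runEpigeneticBattery(co, alternatives = "greater")
  cl <- runEpigeneticBattery(co, alternatives = "less")
  tr <- traitScores(epigeneticView(co))
  idx <- pairIndex(epigeneticView(co))
  noTies <- vapply(seq_len(35L), function(j)
    all(tr[j, idx[1, ]] != tr[j, idx[2, ]]), logical(1))
  pick <- which(cg$scale %in% neoScales()$scale[noTies])
  # tie-free: NotHigher coincides with Lower, so both alternatives test the
  # same counts ...
  expect_equal(cl$x1[pick], cg$x1[pick])
  expect_equal(cl$x2[pick], cg$x2[pick])
  # ... and the "less" p equals the "greater" p of the row-swapped table
  for (i in pick[c(1, 8, 20)]) {
    expect_equal(cl$p_value[i],
                 barnardTest(cl$x2[i], cl$n2[i], cl$x1[i], cl$n1[i],
                             alternative = "greater")$p.value)
  }
})

test_that("a methylation tie excludes the pair from that CpG only", {
  meth <- matrix(rep(c(10, 5), 5 * 4 / 2), 5, 8)
  meth[2, 3:4] <- 0            # pair 2 tied at CpG2 only
  co <- fixtureCohort(4L, meth = meth)
  cells <- runEpigeneticBattery(co, alternatives = "greater")
  expect_true(all(cells$n_pairs_excluded[cells$cpg == 2] == 1L))
  expect_true(all(cells$n_pairs_excluded[cells$cpg != 2] == 0L))
  expect_true(all(cells$n_pairs_used[cells$cpg == 2] == 3L))
})

test_that("the battery runs 350 deterministic cells in canonical order", {
  co <- nullEpiCohort(15L, seed = 47L)
  cells <- runEpigeneticBattery(co)
  expect_equal(nrow(cells), 350L)
  expect_equal(cells$cpg, rep(1:5, each = 70L))
  expect_equal(cells$scale[1:4],
               rep(neoScales()$scale[1:2], each = 2L))
  expect_equal(cells$alternative, rep(c("greater", "less"), 175L))
  expect_identical(cells, runEpigeneticBattery(co))
  expect_true(all(cells$p_value >= 0 & cells$p_value <= 1))
  # optional BH column never alters the defaults
  withBh <- runEpigeneticBattery(co, bh = TRUE)
  expect_identical(withBh[, colnames(cells)], cells)
})

test_that("the mirrored both-twins construction is anti-conservative at the null", {
  # its rows are perfectly dependent (x2 = n1 - x1 on tie-free data), so
  # the two-binomial null understates the variance of p1hat - p2hat; this
  # is the documented reason index_twin is the default
  rej <- vapply(1:40, function(s) {
    co <- nullEpiCohort(35L, seed = 50000L + s)
    mean(runEpigeneticBattery(co,
                              pairContribution = "both_twins")$p_value <
           0.05)
  }, numeric(1))
  expect_gt(mean(rej), 0.06)
})

test_that("a single usable pair yields a no-evidence p-value", {
  co <- fixtureCohort(1L, meth = c(9, 2),
                      traits = list(Warmth = c(20L, 10L)))
  cells <- runEpigeneticBattery(co)
  expect_equal(unique(cells$n_pairs_used), 1L)
  expect_true(all(cells$p_value > 0.2))
})

test_that("significant-cell summaries filter by the raw one-sided p", {
  co <- nullEpiCohort(15L, seed = 53L)
  cells <- runEpigeneticBattery(co)
  expect_equal(nrow(summarizeSignificant(cells, alpha = 0)$table), 0L)
  expect_equal(nrow(summarizeSignificant(cells, alpha = 1)$table), 350L)
  sig <- summarizeSignificant(cells, alpha = 0.2)
  expect_true(all(sig$table$p_value <= 0.2))
  expect_false(is.unsorted(sig$table$p_value))
  expect_equal(sig$bubbles$a + sig$bubbles$b, sig$table$n1)
})
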