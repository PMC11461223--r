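#' Pooled Wald ordering statistic for a 2x2 table
#'
#' `T = (p1hat - p2hat) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with the
#' pooled `phat = (x1 + x2)/(n1 + n2)` — the score statistic that orders
#' tables in the unconditional exact test. Totally degenerate tables
#' (`phat` 0 or 1) take `T = 0` by convention: they carry no evidence of
#' direction.
#'
#' @param x1,n1 successes and size of row 1.
#' @param x2,n2 successes and size of row 2.
#' @return the statistic (scalar).
#' @examples
#' waldStatistic(2, 2, 0, 2)  # 2
#' @export
waldStatistic <- function(x1, n1, x2, n2) {
  .check2x2(x1, n1, x2, n2)
  .tMatrix(n1, n2)[x1 + 1L, x2 + 1L]
}

.check2x2 <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2,
            x1 == round(x1), x2 == round(x2))
}

# T over the full (k1, k2) lattice, rows k1 = 0..n1, cols k2 = 0..n2
.tMatrix <- function(n1, n2) {
  k1 <- 0:n1; k2 <- 0:n2
  pooled <- outer(k1, k2, "+") / (n1 + n2)
  num <- outer(k1 / n1, k2 / n2, "-")
  den <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  tm <- num / den
  tm[pooled == 0 | pooled == 1] <- 0
  tm
}

# extreme-region indicator for a given observed statistic; ties in T are
# included (tolerance absorbs floating-point noise in equal-T tables)
.extremeMask <- function(tm, tObs, alternative, tol = 1e-9) {
  switch(alternative,
         greater   = tm >= tObs - tol,
         less      = tm <= tObs + tol,
         two.sided = abs(tm) >= abs(tObs) - tol)
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Exact test for a difference of two binomial proportions that conditions
#' only on the two group sizes. The p-value is the supremum, over the
#' nuisance common success probability pi in (0, 1), of the total
#' probability of all tables at least as extreme as the observed one under
#' the pooled Wald ordering ([waldStatistic()]); `"two.sided"` uses the
#' `|T|` ordering (not doubling). The supremum is located on a uniform grid
#' over (1e-6, 1 - 1e-6) and then sharpened by golden-section search around
#' the best grid point.
#'
#' @param x1,n1,x2,n2 the 2x2 table: successes/size per row; "success" is
#'   the column whose proportions are compared, and `alternative =
#'   "greater"` means H1: p1 > p2.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @param gridPoints number of nuisance grid points (default 1001).
#' @param refine golden-section refinement around the best grid point.
#' @param useCache memoise the result (used by the battery, where the same
#'   table recurs across cells).
#' @return an object of class `htest`: `statistic` (T), `p.value`,
#'   `estimate` (pi attaining the supremum), `parameter` (grid points),
#'   `alternative`.
#' @examples
#' barnardTest(2, 2, 0, 2, alternative = "greater")$p.value  # 0.0625
#' @export
barnardTest <- function(x1, n1, x2, n2,
                        alternative = c("two.sided", "greater", "less"),
                        gridPoints = 1001L, refine = TRUE,
                        useCache = FALSE) {
  alternative <- match.arg(alternative)
  .check2x2(x1, n1, x2, n2)
  if (useCache) {
    key <- paste(x1, n1, x2, n2, alternative, gridPoints, refine, sep = "/")
    hit <- .twinmethCache[[key]]
    if (!is.null(hit)) return(hit)
  }
  tm <- .tMatrix(n1, n2)
  tObs <- tm[x1 + 1L, x2 + 1L]
  M <- .extremeMask(tm, tObs, alternative)
  eps <- 1e-6
  pis <- seq(eps, 1 - eps, length.out = gridPoints)
  D1 <- vapply(0:n1, function(k) dbinom(k, n1, pis), numeric(gridPoints))
  D2 <- vapply(0:n2, function(k) dbinom(k, n2, pis), numeric(gridPoints))
  pv <- rowSums((D1 %*% M) * D2)
  best <- which.max(pv)
  pSup <- pv[best]
  piSup <- pis[best]
  if (refine) {
    ext <- which(M, arr.ind = TRUE)
    k1e <- ext[, 1L] - 1L
    k2e <- ext[, 2L] - 1L
    f <- function(p) sum(dbinom(k1e, n1, p) * dbinom(k2e, n2, p))
    lo <- pis[max(1L, best - 1L)]
    hi <- pis[min(gridPoints, best + 1L)]
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-12)
    if (opt$objective > pSup) {
      pSup <- opt$objective
      piSup <- opt$maximum
    }
  }
  out <- structure(list(
    statistic = c(T = tObs), p.value = min(1, pSup),
    estimate = c(pi.at.sup = piSup),
    parameter = c(grid.points = gridPoints),
    alternative = alternative,
    method = "Barnard unconditional exact test (pooled Wald ordering)",
    data.name = sprintf("2x2 table (%d/%d, %d/%d)", x1, n1, x2, n2)),
    class = "htest")
  if (useCache) assign(key, out, envir = .twinmethCache)
  out
}

#' Brute-force oracle for the unconditional exact p-value
#'
#' Same definition as [barnardTest()] but computed the slow way: explicit
#' enumeration of the extreme tables and a dense fixed nuisance grid with no
#' refinement. Verification only; guarded to `n1 + n2 <= 60`.
#'
#' @inheritParams barnardTest
#' @param gridPoints dense grid size (default 100001).
#' @return the p-value (scalar).
#' @export
barnardOracle <- function(x1, n1, x2, n2,
                          alternative = c("two.sided", "greater", "less"),
                          gridPoints = 100001L) {
  alternative <- match.arg(alternative)
  .check2x2(x1, n1, x2, n2)
  if (n1 + n2 > 60) stop("oracle size guard: n1 + n2 must be <= 60")
  tm <- .tMatrix(n1, n2)
  tObs <- tm[x1 + 1L, x2 + 1L]
  ext <- which(.extremeMask(tm, tObs, alternative), arr.ind = TRUE)
  eps <- 1e-6
  pis <- seq(eps, 1 - eps, length.out = gridPoints)
  acc <- numeric(gridPoints)
  for (r in seq_len(nrow(ext))) {
    acc <- acc + dbinom(ext[r, 1L] - 1L, n1, pis) *
                 dbinom(ext[r, 2L] - 1L, n2, pis)
  }
  min(1, max(acc))
}

#' Fisher's conditional exact test for a 2x2 table
#'
#' Comparator for the unconditional test: the hypergeometric test
#' conditioning on both margins ([stats::fisher.test()]); two-sided by
#' summing table probabilities not exceeding the observed one.
#'
#' @inheritParams barnardTest
#' @return the p-value (scalar).
#' @examples
#' fisherP(2, 2, 0, 2, alternative = "greater")  # 1/6
#' @export
fisherP <- function(x1, n1, x2, n2,
                    alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  .check2x2(x1, n1, x2, n2)
  m <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
  fisher.test(m, alternative = alternative)$p.value
}
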