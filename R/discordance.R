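#' Orient twin pairs by within-pair methylation rank
#'
#' For one CpG site, labels the higher- and lower-methylation twin of each
#' pair in the epigenetic view. A pair with identical values at that CpG
#' (typically two zeros) is excluded for that CpG only; a pair with a
#' missing value is excluded with reason `"missing methylation"`.
#'
#' @param cohort a [TwinCohort-class] (its epigenetic view is used).
#' @param cpg CpG index, 1..5.
#' @return `data.frame`: `pair_id, high_twin, low_twin, excluded, reason`.
#' @export
orientPairs <- function(cohort, cpg) {
  epi <- epigeneticView(cohort)
  idx <- pairIndex(epi)
  ids <- twinIds(epi)
  m <- methylation(epi)[cpg, ]
  m1 <- m[idx[1, ]]; m2 <- m[idx[2, ]]
  excluded <- is.na(m1) | is.na(m2) | (!is.na(m1) & !is.na(m2) & m1 == m2)
  reason <- ifelse(is.na(m1) | is.na(m2), "missing methylation",
                   ifelse(excluded, "methylation tie", ""))
  hiFirst <- !excluded & m1 > m2
  data.frame(
    pair_id = colnames(idx),
    high_twin = ifelse(excluded, NA, ifelse(hiFirst, ids[idx[1, ]],
                                            ids[idx[2, ]])),
    low_twin = ifelse(excluded, NA, ifelse(hiFirst, ids[idx[2, ]],
                                           ids[idx[1, ]])),
    excluded = excluded, reason = reason,
    stringsAsFactors = FALSE)
}

#' Classify twins by methylation rank and trait status
#'
#' Per-twin discordance labels for one (CpG, scale, alternative) cell. The
#' methylation rank is `H`/`L` within the pair; the trait status follows the
#' alternative-specific tie rule: under `"greater"` the columns are
#' `Higher` / `NotHigher` and trait ties make both twins `NotHigher`; under
#' `"less"` they are `Lower` / `NotLower` with ties going to `NotLower`.
#' Trait ties never exclude a pair — only methylation ties (and missing
#' data) do.
#'
#' @param cohort a [TwinCohort-class].
#' @param cpg CpG index, 1..5.
#' @param scale scale name.
#' @param alternative `"greater"` or `"less"`.
#' @return `data.frame` with two rows per non-excluded pair:
#'   `pair_id, twin_id, meth_rank, trait_status`; excluded pairs appear once
#'   with `excluded = TRUE` and a `reason`.
#' @export
classifyPairs <- function(cohort, cpg, scale,
                          alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  epi <- epigeneticView(cohort)
  ori <- orientPairs(epi, cpg)
  tr <- traitScores(epi, scale)[1, ]
  rows <- lapply(seq_len(nrow(ori)), function(i) {
    if (ori$excluded[i]) {
      return(data.frame(pair_id = ori$pair_id[i], twin_id = NA_character_,
                        meth_rank = NA_character_,
                        trait_status = NA_character_, excluded = TRUE,
                        reason = ori$reason[i], stringsAsFactors = FALSE))
    }
    hT <- tr[ori$high_twin[i]]; lT <- tr[ori$low_twin[i]]
    status <- if (alternative == "greater") {
      c(ifelse(hT > lT, "Higher", "NotHigher"),
        ifelse(lT > hT, "Higher", "NotHigher"))
    } else {
      c(ifelse(hT < lT, "Lower", "NotLower"),
        ifelse(lT < hT, "Lower", "NotLower"))
    }
    data.frame(pair_id = ori$pair_id[i],
               twin_id = c(ori$high_twin[i], ori$low_twin[i]),
               meth_rank = c("H", "L"), trait_status = status,
               excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Core cell counts for one (cpg, scale, alternative).
# m1/t1 refer to the index (first) twin of each pair, m2/t2 to the co-twin.
# Success column is "lower trait" (NotHigher under "greater", Lower under
# "less"), so the "greater" Barnard alternative tests p1 > p2 in the
# higher-DNAm-and-lower-trait sense.
.cellCounts <- function(m1, m2, t1, t2, alternative, pairContribution) {
  exclMiss <- is.na(m1) | is.na(m2) | is.na(t1) | is.na(t2)
  exclTie <- !exclMiss & m1 == m2
  use <- !(exclMiss | exclTie)
  nUsed <- sum(use)
  res <- list(n_pairs_used = nUsed,
              n_pairs_excluded = sum(exclMiss | exclTie),
              n_excluded_missing = sum(exclMiss),
              n_excluded_meth_tie = sum(exclTie))
  if (nUsed == 0L) return(c(res, list(x1 = NA, n1 = 0L, x2 = NA, n2 = 0L)))
  m1 <- m1[use]; m2 <- m2[use]; t1 <- t1[use]; t2 <- t2[use]
  hiFirst <- m1 > m2
  if (pairContribution == "both_twins") {
    tHi <- ifelse(hiFirst, t1, t2)
    tLo <- ifelse(hiFirst, t2, t1)
    if (alternative == "greater") {
      sHi <- !(tHi > tLo); sLo <- !(tLo > tHi)
    } else {
      sHi <- tHi < tLo; sLo <- tLo < tHi
    }
    c(res, list(x1 = sum(sHi), n1 = nUsed, x2 = sum(sLo), n2 = nUsed))
  } else {
    s1 <- if (alternative == "greater") !(t1 > t2) else t1 < t2
    c(res, list(x1 = sum(s1[hiFirst]), n1 = sum(hiFirst),
                x2 = sum(s1[!hiFirst]), n2 = sum(!hiFirst)))
  }
}

#' Build the 2x2 contingency table for one battery cell
#'
#' Rows are methylation rank; the success column is "lower trait" under the
#' cell's alternative-specific tie rule, so the Barnard `"greater"`
#' alternative tests whether the higher-methylation twin is more likely to
#' be the lower-trait twin (H1: p1 > p2) and `"less"` the reverse.
#'
#' Two constructions are supported. `"index_twin"` (default): one
#' observation per pair — rows split pairs by whether the first (index)
#' twin is the higher-methylation twin, and the column records that twin's
#' trait status; this is the four-way pair classification of the motivating
#' study, and under the null the two rows are conditionally independent
#' binomials, so the unconditional test keeps its size guarantee.
#' `"both_twins"`: each pair contributes one observation to each row
#' (fixed, mirrored rows); the rows are then perfectly dependent and the
#' test is anti-conservative — retained for comparison only (see vignette).
#'
#' @param cohort a [TwinCohort-class].
#' @param cpg CpG index, 1..5.
#' @param scale scale name.
#' @param alternative `"greater"` or `"less"`.
#' @param pairContribution `"index_twin"` or `"both_twins"`.
#' @return one-row `data.frame`: `cpg, scale, alternative, x1, n1, x2, n2,
#'   n_pairs_used, n_pairs_excluded`.
#' @export
buildContingency <- function(cohort, cpg, scale,
                             alternative = c("greater", "less"),
                             pairContribution = c("index_twin",
                                                  "both_twins")) {
  alternative <- match.arg(alternative)
  pairContribution <- match.arg(pairContribution)
  epi <- epigeneticView(cohort)
  if (nPairs(epi) == 0L) stop("empty epigenetic view")
  idx <- pairIndex(epi)
  m <- methylation(epi)[cpg, ]
  tr <- traitScores(epi, scale)[1, ]
  cc <- .cellCounts(m[idx[1, ]], m[idx[2, ]], tr[idx[1, ]], tr[idx[2, ]],
                    alternative, pairContribution)
  if (cc$n_pairs_used == 0L) stop("zero usable pairs for this cell")
  data.frame(cpg = cpg, scale = scale, alternative = alternative,
             x1 = cc$x1, n1 = cc$n1, x2 = cc$x2, n2 = cc$n2,
             n_pairs_used = cc$n_pairs_used,
             n_pairs_excluded = cc$n_pairs_excluded,
             stringsAsFactors = FALSE)
}

#' Run the within-pair methylation discordance battery
#'
#' 5 CpG sites x 35 scales x the requested alternatives, each cell a 2x2
#' table ([buildContingency()]) tested with Barnard's unconditional exact
#' test. Exclusions (methylation ties, missing values) are applied per cell.
#' Output is deterministically ordered: CpG, catalog scale order,
#' alternative. No multiplicity correction is applied to the battery by
#' default (the reported p are raw one-sided unconditional p-values);
#' `bh = TRUE` appends a labelled Benjamini-Hochberg column without altering
#' the default columns.
#'
#' @param cohort a [TwinCohort-class] with a non-empty epigenetic view.
#' @param alternatives subset of `c("greater", "less")`.
#' @param pairContribution see [buildContingency()].
#' @param gridPoints nuisance grid size for [barnardTest()].
#' @param bh append a Benjamini-Hochberg adjusted column `p_bh`.
#' @return `data.frame`, one row per cell: the [buildContingency()] columns
#'   plus `domain, statistic, p_value` (and `p_bh` if requested). Cells with
#'   an empty table row (all index twins on one methylation side) get
#'   `p_value = 1` and a `note`.
#' @export
runEpigeneticBattery <- function(cohort,
                                 alternatives = c("greater", "less"),
                                 pairContribution = c("index_twin",
                                                      "both_twins"),
                                 gridPoints = 1001L, bh = FALSE) {
  pairContribution <- match.arg(pairContribution)
  alternatives <- match.arg(alternatives, c("greater", "less"),
                            several.ok = TRUE)
  epi <- epigeneticView(cohort)
  if (nPairs(epi) == 0L) stop("empty epigenetic view")
  idx <- pairIndex(epi)
  methAll <- methylation(epi)
  trAll <- traitScores(epi)
  cat35 <- neoScales()
  nCell <- 5L * 35L * length(alternatives)
  colCpg <- integer(nCell); colScale <- character(nCell)
  colDom <- character(nCell); colAlt <- character(nCell)
  colX1 <- colN1 <- colX2 <- colN2 <- colUsed <- colExcl <- integer(nCell)
  colStat <- colP <- numeric(nCell); colNote <- character(nCell)
  r <- 0L
  for (cpg in 1:5) {
    m1 <- methAll[cpg, idx[1, ]]
    m2 <- methAll[cpg, idx[2, ]]
    for (j in seq_len(35L)) {
      t1 <- trAll[j, idx[1, ]]
      t2 <- trAll[j, idx[2, ]]
      for (alt in alternatives) {
        cc <- .cellCounts(m1, m2, t1, t2, alt, pairContribution)
        note <- ""
        if (cc$n_pairs_used == 0L || cc$n1 == 0L || cc$n2 == 0L) {
          stat <- NA_real_; p <- 1
          note <- "degenerate table (empty row)"
        } else {
          bt <- barnardTest(cc$x1, cc$n1, cc$x2, cc$n2, alternative = alt,
                            gridPoints = gridPoints, useCache = TRUE)
          stat <- unname(bt$statistic); p <- bt$p.value
        }
        r <- r + 1L
        colCpg[r] <- cpg; colScale[r] <- cat35$scale[j]
        colDom[r] <- cat35$domain[j]; colAlt[r] <- alt
        colX1[r] <- if (is.na(cc$x1)) NA_integer_ else cc$x1
        colN1[r] <- cc$n1
        colX2[r] <- if (is.na(cc$x2)) NA_integer_ else cc$x2
        colN2[r] <- cc$n2
        colUsed[r] <- cc$n_pairs_used; colExcl[r] <- cc$n_pairs_excluded
        colStat[r] <- stat; colP[r] <- p; colNote[r] <- note
      }
    }
  }
  out <- data.frame(
    cpg = colCpg, scale = colScale, domain = colDom, alternative = colAlt,
    x1 = colX1, n1 = colN1, x2 = colX2, n2 = colN2,
    n_pairs_used = colUsed, n_pairs_excluded = colExcl,
    statistic = colStat, p_value = colP, note = colNote,
    stringsAsFactors = FALSE)
  if (bh) out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Filter and package significant battery cells
#'
#' Keeps cells with `p_value <= alpha` (per alternative, raw p) and prepares
#' bubble-chart records: each significant cell's four counts
#' (`a` = row H success, `b` = row H other, `c` = row L success,
#' `d` = row L other) as bubble sizes.
#'
#' @param cells output of [runEpigeneticBattery()].
#' @param alpha significance threshold on the raw one-sided p.
#' @return `list(table = data.frame sorted by p, bubbles = data.frame of
#'   bubble records)`.
#' @export
summarizeSignificant <- function(cells, alpha = 0.05) {
  keep <- cells[!is.na(cells$p_value) & cells$p_value <= alpha, , drop = FALSE]
  keep <- keep[order(keep$p_value), , drop = FALSE]
  bubbles <- data.frame(
    cpg = keep$cpg, scale = keep$scale, alternative = keep$alternative,
    a = keep$x1, b = keep$n1 - keep$x1,
    c = keep$x2, d = keep$n2 - keep$x2,
    p = keep$p_value, stringsAsFactors = FALSE)
  list(table = keep, bubbles = bubbles)
}
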