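#' TwinCohort: a twin cohort with genotype, methylation and trait data
#'
#' S4 container for a per-twin cohort, extending
#' [SummarizedExperiment::SummarizedExperiment]. Columns are twins; the
#' `"methylation"` assay holds percent DNA methylation (0--100, `NA` when
#' unassayed) at the five CpG sites of the MB-COMT promoter pyrosequencing
#' assay (rows `CpG1`..`CpG5`); `colData` carries `twin_id`, `pair_id`,
#' `zygosity` (`"MZ"`/`"DZ"`), `sex` (`"F"`/`"M"`), `age` (years, >= 18),
#' `genotype` (`"Met/Met"`, `"Met/Val"`, `"Val/Val"` or `NA`) and the 35
#' `neo_*` NEO-PI-R scale scores.
#'
#' Validity requires every `pair_id` to occur exactly twice with equal
#' zygosity, unique `twin_id`s, ages >= 18, methylation within \[0, 100\]
#' and trait scores within their catalog ranges.
#'
#' @aliases TwinCohort-class
#' @export
setClass("TwinCohort", contains = "SummarizedExperiment")

.CPG_SITES <- paste0("CpG", 1:5)
.GENOTYPES <- c("Met/Met", "Met/Val", "Val/Val")
.REQUIRED_COLS <- c("twin_id", "pair_id", "zygosity", "sex", "age", "genotype")

.validTwinCohort <- function(object) {
  msg <- character(0)
  cd <- SummarizedExperiment::colData(object)
  if (!all(.REQUIRED_COLS %in% colnames(cd)))
    return(paste("colData must contain:",
                 paste(setdiff(.REQUIRED_COLS, colnames(cd)), collapse = ", ")))
  if (!"methylation" %in% SummarizedExperiment::assayNames(object))
    return("assay 'methylation' is required")
  meth <- SummarizedExperiment::assay(object, "methylation")
  if (nrow(meth) != 5L)
    msg <- c(msg, "methylation assay must have exactly 5 CpG rows")
  mm <- meth[!is.na(meth)]
  if (length(mm) && (min(mm) < 0 || max(mm) > 100))
    msg <- c(msg, "methylation values must lie in [0, 100]")
  if (anyDuplicated(cd$twin_id))
    msg <- c(msg, "duplicated twin_id")
  tab <- table(cd$pair_id)
  if (length(tab) && any(tab != 2L))
    msg <- c(msg, "every pair_id must occur exactly twice")
  zyg <- split(as.character(cd$zygosity), as.character(cd$pair_id))
  if (any(!vapply(zyg, function(z) length(unique(z)) == 1L, logical(1))))
    msg <- c(msg, "co-twins must share zygosity")
  if (!all(cd$zygosity %in% c("MZ", "DZ")))
    msg <- c(msg, "zygosity must be 'MZ' or 'DZ'")
  if (!all(cd$sex %in% c("F", "M")))
    msg <- c(msg, "sex must be 'F' or 'M'")
  if (any(cd$age < 18, na.rm = TRUE))
    msg <- c(msg, "all ages must be >= 18")
  gt <- cd$genotype
  if (!all(is.na(gt) | gt %in% .GENOTYPES))
    msg <- c(msg, "genotype must be Met/Met, Met/Val, Val/Val or NA")
  cat35 <- neoScales()
  missingScales <- setdiff(cat35$column, colnames(cd))
  if (length(missingScales)) {
    msg <- c(msg, paste("missing trait columns:",
                        paste(head(missingScales, 3L), collapse = ", ")))
  } else {
    for (i in seq_len(nrow(cat35))) {
      v <- cd[[cat35$column[i]]]
      if (any(v < cat35$min[i] | v > cat35$max[i], na.rm = TRUE)) {
        msg <- c(msg, paste0(cat35$column[i], " outside [",
                             cat35$min[i], ", ", cat35$max[i], "]"))
      }
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("TwinCohort", .validTwinCohort)

#' Construct a TwinCohort from per-twin data
#'
#' @param twins `data.frame` with one row per twin: columns `twin_id`,
#'   `pair_id`, `zygosity`, `sex`, `age`, `genotype` and the 35 `neo_*`
#'   trait columns (see [neoScales()]).
#' @param methylation optional numeric matrix, 5 CpG rows x one column per
#'   twin (in `twins` row order), percent methylation; `NULL` for a cohort
#'   with no methylation data.
#' @return A validated [TwinCohort-class] object. Twin order (and hence the
#'   "first twin" of each pair, used by the discordance analysis) is the row
#'   order of `twins`.
#' @examples
#' cohort <- genCohort(simulationConfig(nPairsTotal = 6, nEpiPairs = 2,
#'                                      seed = 1))$cohort
#' cohort
#' @export
TwinCohort <- function(twins, methylation = NULL) {
  stopifnot(is.data.frame(twins))
  n <- nrow(twins)
  if (is.null(methylation)) {
    methylation <- matrix(NA_real_, nrow = 5L, ncol = n)
  }
  methylation <- as.matrix(methylation)
  rownames(methylation) <- .CPG_SITES
  colnames(methylation) <- twins$twin_id
  cd <- S4Vectors::DataFrame(twins, row.names = twins$twin_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(methylation = methylation),
    colData = cd)
  methods::new("TwinCohort", se)
}

#' @describeIn TwinCohort number of twin pairs in the cohort.
#' @param x,object a `TwinCohort`.
#' @export
nPairs <- function(x) length(unique(SummarizedExperiment::colData(x)$pair_id))

#' @describeIn TwinCohort twin identifiers.
#' @export
twinIds <- function(x) as.character(SummarizedExperiment::colData(x)$twin_id)

#' @describeIn TwinCohort pair identifiers (one per twin).
#' @export
pairIds <- function(x) as.character(SummarizedExperiment::colData(x)$pair_id)

#' @describeIn TwinCohort zygosity per twin (`"MZ"`/`"DZ"`).
#' @export
zygosities <- function(x) as.character(SummarizedExperiment::colData(x)$zygosity)

#' @describeIn TwinCohort genotype call per twin
#'   (`"Met/Met"`, `"Met/Val"`, `"Val/Val"` or `NA`).
#' @export
genotypeCalls <- function(x) as.character(SummarizedExperiment::colData(x)$genotype)

#' @describeIn TwinCohort the 5 x n percent-methylation matrix.
#' @export
methylation <- function(x) SummarizedExperiment::assay(x, "methylation")

#' Trait score matrix
#'
#' @param x a [TwinCohort-class].
#' @param scales scales to extract (display or column names); default all 35
#'   in catalog order.
#' @return numeric matrix, scales x twins, rownames = `neo_*` columns.
#' @export
traitScores <- function(x, scales = NULL) {
  cols <- if (is.null(scales)) neoScales()$column else resolveScales(scales)
  cd <- SummarizedExperiment::colData(x)
  m <- t(as.matrix(as.data.frame(cd[, cols, drop = FALSE])))
  colnames(m) <- twinIds(x)
  m
}

#' Column indices of each twin pair
#'
#' @param x a [TwinCohort-class].
#' @return integer matrix 2 x nPairs; row 1 is the first ("index") twin of
#'   each pair in cohort column order, row 2 the co-twin. Column names are
#'   pair ids, ordered by first appearance.
#' @export
pairIndex <- function(x) {
  pid <- pairIds(x)
  ord <- split(seq_along(pid), factor(pid, levels = unique(pid)))
  vapply(ord, function(i) i[1:2], integer(2))
}

#' The epigenetic view of a cohort
#'
#' Subsets a cohort to the monozygotic pairs in which both twins have a
#' complete methylation profile (all 5 CpG sites) and complete trait data —
#' the sample on which the within-pair discordance battery operates.
#'
#' @param x a [TwinCohort-class].
#' @return a `TwinCohort` containing only the qualifying MZ pairs.
#' @export
epigeneticView <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  meth <- methylation(x)
  okTwin <- zygosities(x) == "MZ" &
    colSums(is.na(meth)) == 0L &
    complete.cases(as.data.frame(cd[, neoScales()$column, drop = FALSE]))
  okPair <- vapply(split(okTwin, pairIds(x)), all, logical(1))
  keep <- okPair[pairIds(x)]
  x[, keep]
}

setMethod("show", "TwinCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  nMeth <- sum(colSums(is.na(methylation(object))) == 0L)
  cat("TwinCohort with", ncol(object), "twins in", nPairs(object), "pairs\n")
  cat("  zygosity: ", sum(cd$zygosity == "MZ"), " MZ / ",
      sum(cd$zygosity == "DZ"), " DZ twins\n", sep = "")
  cat("  genotyped:", sum(!is.na(cd$genotype)),
      " | complete methylation profiles:", nMeth, "\n")
  cat("  epigenetic view:", nPairs(epigeneticView(object)), "MZ pairs\n")
})
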