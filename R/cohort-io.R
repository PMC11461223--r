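#' Read a twin cohort from CSV
#'
#' The cohort file is wide, comma-separated, UTF-8, one row per twin, with
#' columns `pair_id`, `twin_id`, `zygosity`, `sex`, `age`, `genotype`,
#' `cpg1`..`cpg5` and the 35 `neo_*` scale columns. Missing values are empty
#' cells. A twin with missing CpG values stays in the cohort (it is simply
#' absent from the epigenetic view); rows violating hard invariants (age
#' < 18, scores out of range, pairs without exactly two members) are dropped
#' with a warning, or raise an error under `strict = TRUE`.
#'
#' @param path path to the cohort CSV.
#' @param strict logical; error on any invalid row instead of dropping it.
#' @return a validated [TwinCohort-class].
#' @export
readCohortCsv <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  # sex "F" must not be parsed as logical FALSE
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(twin_id = "character",
                                pair_id = "character",
                                zygosity = "character",
                                sex = "character",
                                genotype = "character"))
  cpgCols <- paste0("cpg", 1:5)
  needed <- c(.REQUIRED_COLS, cpgCols, neoScales()$column)
  missingCols <- setdiff(needed, colnames(df))
  if (length(missingCols))
    stop("cohort CSV lacks mandatory column(s): ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(df$twin_id))
    stop("duplicated twin_id in cohort CSV")

  df$genotype <- .canonGenotype(df$genotype)
  bad <- rep(FALSE, nrow(df))
  why <- rep("", nrow(df))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- FALSE
    why[cond & !bad] <<- reason
    bad <<- bad | cond
  }
  flag(!(df$zygosity %in% c("MZ", "DZ")), "invalid zygosity")
  flag(!(df$sex %in% c("F", "M")), "invalid sex")
  flag(is.na(df$age) | df$age < 18, "age below 18 or missing")
  flag(!is.na(df$genotype) & !(df$genotype %in% .GENOTYPES),
       "unrecognised genotype")
  for (cc in cpgCols)
    flag(!is.na(df[[cc]]) & (df[[cc]] < 0 | df[[cc]] > 100),
         "methylation outside [0, 100]")
  cat35 <- neoScales()
  for (i in seq_len(nrow(cat35))) {
    v <- df[[cat35$column[i]]]
    flag(!is.na(v) & (v < cat35$min[i] | v > cat35$max[i]),
         paste(cat35$column[i], "out of range"))
  }
  if (any(bad)) {
    detail <- paste0(df$twin_id[bad], " (", why[bad], ")", collapse = "; ")
    if (strict) stop("invalid twin row(s): ", detail)
    warning("dropping invalid twin row(s): ", detail)
    df <- df[!bad, , drop = FALSE]
  }
  # a pair needs both members; singletons (incl. pairs broken above) go too
  tab <- table(df$pair_id)
  broken <- names(tab)[tab != 2L]
  if (length(broken)) {
    if (strict) stop("pair(s) without exactly 2 members: ",
                     paste(broken, collapse = ", "))
    warning("dropping pair(s) without exactly 2 members: ",
            paste(broken, collapse = ", "))
    df <- df[!(df$pair_id %in% broken), , drop = FALSE]
  }
  meth <- t(as.matrix(df[, cpgCols, drop = FALSE]))
  TwinCohort(df[, setdiff(colnames(df), cpgCols), drop = FALSE], meth)
}

.canonGenotype <- function(g) {
  g <- trimws(as.character(g))
  g[g == ""] <- NA_character_
  key <- toupper(gsub("[^A-Za-z]", "", g))
  map <- c(METMET = "Met/Met", METVAL = "Met/Val", VALMET = "Met/Val",
           VALVAL = "Val/Val")
  out <- unname(map[key])
  out[is.na(g)] <- NA_character_
  ifelse(is.na(out) & !is.na(g), g, out)
}

#' Write a twin cohort to CSV
#'
#' Inverse of [readCohortCsv()]: one row per twin, methylation in
#' `cpg1`..`cpg5`, missing values as empty cells. Deterministic column order.
#'
#' @param cohort a [TwinCohort-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCohortCsv <- function(cohort, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  meth <- t(methylation(cohort))
  colnames(meth) <- paste0("cpg", 1:5)
  df <- cbind(cd[, .REQUIRED_COLS, drop = FALSE], meth,
              cd[, neoScales()$column, drop = FALSE])
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write analysis result tables to CSV
#'
#' Serialises a result table with the print conventions of the association
#' battery: p-value columns to 4 decimals, effect-size and CI columns to 3
#' decimals, everything else untouched. Columns keep their input order.
#'
#' @param rows a `data.frame` of results (may be empty: header-only file).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResultsCsv <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  pCols <- grepl("^p($|_|\\.)|p_value|p_bonf", colnames(out))
  eCols <- grepl("effect|_ci_|^d$|^r$", colnames(out)) & !pCols
  for (j in seq_along(out)) {
    if (!is.numeric(out[[j]])) next
    if (pCols[j]) out[[j]] <- .fmtNum(out[[j]], 4L)
    else if (eCols[j]) out[[j]] <- .fmtNum(out[[j]], 3L)
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.fmtNum <- function(x, digits) {
  ifelse(is.na(x), NA_character_,
         formatC(round(x, digits), format = "f", digits = digits))
}

#' Export contingency tables as JSON records
#'
#' One record per battery cell:
#' `{cpg, scale, alternative, a, b, c, d, n_pairs_excluded, p}`, where
#' `a`..`d` are the 2x2 counts (row 1: higher-methylation /
#' index-twin-higher-methylation; "success" column first).
#'
#' @param cells battery cell table from [runEpigeneticBattery()].
#' @param path output path for the JSON file.
#' @return the path, invisibly.
#' @export
exportContingencyJson <- function(cells, path) {
  recs <- data.frame(
    cpg = cells$cpg, scale = cells$scale, alternative = cells$alternative,
    a = cells$x1, b = cells$n1 - cells$x1,
    c = cells$x2, d = cells$n2 - cells$x2,
    n_pairs_excluded = cells$n_pairs_excluded, p = cells$p_value)
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Locate assayed CpG positions in a pyrosequencing dispensation sequence
#'
#' In a bisulfite pyrosequencing "sequence to analyze", each assayed CpG
#' cytosine appears as the IUPAC degenerate symbol `Y` (C/T, the two states
#' a methylated vs unmethylated cytosine takes after bisulfite conversion
#' and PCR). The positions of `Y` therefore enumerate the assayed sites.
#'
#' @param assaySequence a nucleotide string over `A C G T Y R N`
#'   (case-insensitive).
#' @return integer vector of 1-based `Y` positions, ascending.
#' @examples
#' findCpgPositions("TYGGGYGGGTYGTYGYGGGAGAGGTGAGAG")  # the 5 assayed sites
#' @export
findCpgPositions <- function(assaySequence) {
  stopifnot(is.character(assaySequence), length(assaySequence) == 1L)
  chars <- strsplit(toupper(assaySequence), "")[[1]]
  illegal <- setdiff(unique(chars), c("A", "C", "G", "T", "Y", "R", "N"))
  if (length(illegal))
    stop("illegal character(s) in assay sequence: ",
         paste(illegal, collapse = ", "))
  which(chars == "Y")
}
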