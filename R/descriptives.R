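#' Descriptive statistics in the study's table convention
#'
#' Mean, median, sample SD (n-1), min, max, skewness and excess kurtosis.
#' Skewness is the adjusted Fisher-Pearson standardised third moment (G1)
#' and kurtosis the sample-adjusted excess kurtosis (G2), so a normal sample
#' has `Ku` near 0 (both via `e1071`, type 2). `Ku` is `NA` for n < 4.
#'
#' @param x numeric vector, no missing values, n >= 2, non-constant.
#' @return one-row `data.frame` with columns `M, Mdn, s, Min, Max, Sk, Ku`.
#' @export
describeVector <- function(x) {
  if (anyNA(x)) stop("missing values not allowed")
  n <- length(x)
  if (n < 2L) stop("insufficient data: need n >= 2")
  if (var(x) == 0) stop("constant vector: skewness/kurtosis undefined")
  data.frame(
    M = mean(x), Mdn = median(x), s = sd(x), Min = min(x), Max = max(x),
    Sk = e1071::skewness(x, type = 2),
    Ku = if (n >= 4L) e1071::kurtosis(x, type = 2) else NA_real_)
}

#' Cohort descriptive table (methylation + trait scales)
#'
#' One [describeVector()] row per variable, over all twins with a
#' non-missing value. Default variables mirror the study's descriptive
#' table: the five CpG sites and the five domains.
#'
#' @param cohort a [TwinCohort-class].
#' @param vars character vector of variables: any of `cpg1`..`cpg5` and
#'   scale names.
#' @return `data.frame` with a `variable` column plus the describe columns.
#' @export
describeCohort <- function(cohort,
                           vars = c(paste0("cpg", 1:5),
                                    neoScales()$scale[neoScales()$type ==
                                                        "domain"])) {
  meth <- methylation(cohort)
  rows <- lapply(vars, function(v) {
    x <- if (grepl("^cpg[1-5]$", tolower(v))) {
      meth[as.integer(sub("cpg", "", tolower(v))), ]
    } else {
      traitScores(cohort, v)[1, ]
    }
    cbind(variable = v, describeVector(x[!is.na(x)]))
  })
  do.call(rbind, rows)
}

#' Normality gate (Shapiro-Wilk)
#'
#' @param x numeric vector, n >= 3.
#' @param alpha gate level; the gate passes iff p >= alpha.
#' @return `list(p, pass)`. A constant sample cannot be assessed and fails
#'   the gate by convention (`p = NA`), routing downstream comparisons to
#'   the nonparametric test.
#' @export
normalityGate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("insufficient data: Shapiro-Wilk needs n >= 3")
  if (var(x) == 0) return(list(p = NA_real_, pass = FALSE))
  p <- shapiro.test(x)$p.value
  list(p = p, pass = p >= alpha)
}

#' Variance homogeneity gate (Levene, mean-centred)
#'
#' @param x,y the two samples (each n >= 2).
#' @param alpha gate level; passes iff p >= alpha.
#' @return `list(p, pass)`. If the absolute mean-deviations are constant
#'   across both samples (e.g. two constant samples) the gate passes by
#'   convention (`p = 1`).
#' @export
varianceGate <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("insufficient data: both samples need n >= 2")
  dev <- c(abs(x - mean(x)), abs(y - mean(y)))
  if (var(dev) == 0) return(list(p = 1, pass = TRUE))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  p <- car::leveneTest(c(x, y), g, center = mean)[1, "Pr(>F)"]
  list(p = p, pass = p >= alpha)
}

#' Assumption-gated test selection for a two-group comparison
#'
#' Routing rule of the association battery: if Shapiro-Wilk rejects
#' normality in either group, use Mann-Whitney U; otherwise, if the
#' mean-centred Levene test rejects variance homogeneity, use Welch's t;
#' otherwise the pooled-variance Student t.
#'
#' @param x,y the two samples.
#' @param gateAlpha level of both gates (default 0.05).
#' @return `list(normality_p = c(x=, y=), variance_p, decision, gate_alpha)`
#'   with `decision` one of `"student_t"`, `"welch_t"`, `"mann_whitney"`.
#' @export
chooseTest <- function(x, y, gateAlpha = 0.05) {
  nx <- normalityGate(x, gateAlpha)
  ny <- normalityGate(y, gateAlpha)
  vg <- varianceGate(x, y, gateAlpha)
  decision <- if (!nx$pass || !ny$pass) "mann_whitney"
              else if (!vg$pass) "welch_t"
              else "student_t"
  list(normality_p = c(x = nx$p, y = ny$p),
       variance_p = vg$p, decision = decision, gate_alpha = gateAlpha)
}
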