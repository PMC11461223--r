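#' Simulation configuration for synthetic twin cohorts
#'
#' Holds every knob of the cohort generator. Defaults reproduce the study
#' conditions of the motivating cohort: 215 twin pairs (430 twins, 75.8%
#' monozygotic), an epigenetic subsample of 35 MZ pairs, Met allele
#' frequency 482/860, NEO-PI-R domain moments matching the published
#' descriptive table, per-CpG zero-inflated lognormal percent-methylation
#' moment-matched to the published means/SDs, and within-pair trait ICC 0.5.
#'
#' @aliases SimulationConfig-class
#' @export
setClass("SimulationConfig", representation(
  nPairsTotal = "integer",
  fractionMz = "numeric",
  nEpiPairs = "integer",
  pMet = "numeric",
  traitMeans = "numeric",
  traitSds = "numeric",
  iccMz = "numeric",
  methLogMean = "numeric",
  methLogSd = "numeric",
  methZeroMass = "numeric",
  methPairCorr = "numeric",
  plantedEffect = "ANY",
  groupShift = "ANY",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  cols <- neoScales()$column
  if (object@nPairsTotal < 1L) msg <- c(msg, "nPairsTotal must be >= 1")
  if (object@fractionMz < 0 || object@fractionMz > 1)
    msg <- c(msg, "fractionMz must be in [0, 1]")
  if (object@pMet <= 0 || object@pMet >= 1)
    msg <- c(msg, "pMet must be in (0, 1)")
  nMz <- round(object@nPairsTotal * object@fractionMz)
  if (object@nEpiPairs > nMz)
    msg <- c(msg, "nEpiPairs cannot exceed the number of MZ pairs")
  if (!identical(sort(names(object@traitMeans)), sort(cols)) ||
      !identical(sort(names(object@traitSds)), sort(cols)) ||
      !identical(sort(names(object@iccMz)), sort(cols)))
    msg <- c(msg, "traitMeans/traitSds/iccMz must be named by all 35 scales")
  if (any(object@traitSds <= 0)) msg <- c(msg, "trait SDs must be > 0")
  if (any(abs(object@iccMz) > 1)) msg <- c(msg, "iccMz must be in [-1, 1]")
  if (length(object@methLogMean) != 5L || length(object@methLogSd) != 5L ||
      length(object@methZeroMass) != 5L)
    msg <- c(msg, "methylation parameter vectors must have length 5")
  if (any(object@methLogSd <= 0)) msg <- c(msg, "methLogSd must be > 0")
  if (any(object@methZeroMass < 0 | object@methZeroMass >= 1))
    msg <- c(msg, "methZeroMass must be in [0, 1)")
  if (object@methPairCorr < 0 || object@methPairCorr >= 1)
    msg <- c(msg, "methPairCorr must be in [0, 1)")
  pe <- object@plantedEffect
  if (!is.null(pe)) {
    if (!all(c("cpg", "scale", "delta", "direction") %in% names(pe)))
      msg <- c(msg, "plantedEffect needs cpg, scale, delta, direction")
    else {
      if (pe$delta < 0 || pe$delta > 0.5)
        msg <- c(msg, "plantedEffect delta must be in [0, 0.5]")
      if (!pe$direction %in% c("greater", "less"))
        msg <- c(msg, "plantedEffect direction must be 'greater' or 'less'")
    }
  }
  gs <- object@groupShift
  if (!is.null(gs) && !all(c("scale", "deltaInSd") %in% names(gs)))
    msg <- c(msg, "groupShift needs scale and deltaInSd")
  if (length(msg)) msg else TRUE
})

# Published-style moments the methylation generator is matched to:
# per-CpG mean and SD of percent methylation (lognormal moment matching).
.methMoments <- function() {
  list(mean = c(7.75, 4.55, 6.18, 6.16, 4.40),
       sd   = c(6.43, 4.58, 5.47, 5.21, 4.22))
}

#' @rdname SimulationConfig-class
#' @param nPairsTotal total number of twin pairs.
#' @param fractionMz fraction of pairs that are monozygotic.
#' @param nEpiPairs number of MZ pairs given methylation data (`NULL`:
#'   35, capped at the MZ pair count).
#' @param pMet Met allele frequency used for the Hardy-Weinberg genotype draw.
#' @param traitMeans,traitSds,iccMz named numeric vectors over the 35 scale
#'   columns: generating mean, SD and MZ within-pair correlation per scale
#'   (DZ pairs use `iccMz / 2`). Defaults: published domain moments, facets
#'   at mean/6 and SD/sqrt(6), ICC 0.5 everywhere.
#' @param methLogMean,methLogSd log-scale location/scale of the lognormal
#'   percent-methylation model per CpG site (defaults moment-matched to the
#'   published per-CpG mean/SD).
#' @param methZeroMass per-CpG probability that a value is an exact zero
#'   (assay floor), default 0.05.
#' @param methPairCorr within-pair correlation of percent methylation,
#'   default 0.4 (the source study reports none; this default is a package
#'   choice, not an estimate).
#' @param plantedEffect `NULL`, or `list(cpg =, scale =, delta =,
#'   direction =)` planting a methylation-trait discordance effect, see
#'   [plantDiscordanceEffect()].
#' @param groupShift `NULL`, or `list(scale =, deltaInSd =)` adding a crude
#'   mean shift (in generating-SD units) to the Met/Met group on one scale,
#'   for power studies of the SNP battery.
#' @param seed integer seed; all sub-generators derive their own streams
#'   from it (see [genCohort()]).
#' @return `simulationConfig()` returns a validated `SimulationConfig`.
#' @export
simulationConfig <- function(nPairsTotal = 215L,
                             fractionMz = 0.758,
                             nEpiPairs = NULL,
                             pMet = 482 / 860,
                             traitMeans = NULL,
                             traitSds = NULL,
                             iccMz = NULL,
                             methLogMean = NULL,
                             methLogSd = NULL,
                             methZeroMass = rep(0.05, 5L),
                             methPairCorr = 0.4,
                             plantedEffect = NULL,
                             groupShift = NULL,
                             seed = 1L) {
  if (is.null(nEpiPairs))
    nEpiPairs <- min(35L, as.integer(round(nPairsTotal * fractionMz)))
  cat35 <- neoScales()
  domM <- c(Neuroticism = 87.31, Extraversion = 118.04, Openness = 114.60,
            Agreeableness = 115.04, Conscientiousness = 122.26)
  domS <- c(Neuroticism = 20.21, Extraversion = 17.67, Openness = 14.96,
            Agreeableness = 14.34, Conscientiousness = 20.13)
  defM <- ifelse(cat35$type == "domain", domM[cat35$domain],
                 domM[cat35$domain] / 6)
  defS <- ifelse(cat35$type == "domain", domS[cat35$domain],
                 domS[cat35$domain] / sqrt(6))
  names(defM) <- names(defS) <- cat35$column
  if (is.null(traitMeans)) traitMeans <- defM
  if (is.null(traitSds)) traitSds <- defS
  if (is.null(iccMz)) iccMz <- setNames(rep(0.5, 35L), cat35$column)
  mm <- .methMoments()
  logSd2 <- log(1 + (mm$sd / mm$mean)^2)
  if (is.null(methLogSd)) methLogSd <- sqrt(logSd2)
  if (is.null(methLogMean)) methLogMean <- log(mm$mean) - logSd2 / 2
  methods::new("SimulationConfig",
               nPairsTotal = as.integer(nPairsTotal),
               fractionMz = fractionMz, nEpiPairs = as.integer(nEpiPairs),
               pMet = pMet, traitMeans = traitMeans, traitSds = traitSds,
               iccMz = iccMz, methLogMean = methLogMean,
               methLogSd = methLogSd, methZeroMass = methZeroMass,
               methPairCorr = methPairCorr, plantedEffect = plantedEffect,
               groupShift = groupShift, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nPairsTotal, "pairs (",
      round(100 * object@fractionMz, 1), "% MZ ),",
      object@nEpiPairs, "epigenetic pairs, pMet =",
      signif(object@pMet, 4), "\n")
  if (!is.null(object@plantedEffect))
    cat("  planted effect: CpG", object@plantedEffect$cpg, "x",
        object@plantedEffect$scale, "delta =", object@plantedEffect$delta,
        "direction =", object@plantedEffect$direction, "\n")
  if (!is.null(object@groupShift))
    cat("  genotype group shift:", object@groupShift$scale, "by",
        object@groupShift$deltaInSd, "SD\n")
  cat("  seed:", object@seed, "\n")
})

# Deterministic sub-stream seed: a labelled hash of the global seed, kept
# below 2^31 so it is a valid R integer seed. Adding a generator does not
# perturb the draws of the others.
.streamSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (31^(seq_along(utf8ToInt(label)) %% 7)))
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483629)
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' i.i.d. genotype calls with probabilities (p^2, 2pq, q^2) for
#' (Met/Met, Met/Val, Val/Val), p = Met allele frequency.
#'
#' @param n number of independent draws.
#' @param pMet Met allele frequency, in (0, 1).
#' @param seed integer seed.
#' @return character vector of genotype calls.
#' @export
genGenotypesHwe <- function(n, pMet, seed) {
  if (pMet <= 0 || pMet >= 1) stop("pMet must be in (0, 1)")
  set.seed(seed)
  q <- 1 - pMet
  sample(.GENOTYPES, n, replace = TRUE,
         prob = c(pMet^2, 2 * pMet * q, q^2))
}

#' Draw within-pair correlated trait scores
#'
#' Pairs from a bivariate normal with common mean/SD and correlation `icc`,
#' rounded to integers and clipped to the scale range. The empirical
#' cross-twin correlation converges to `icc` before rounding/clipping
#' distortion.
#'
#' @param nPairs number of pairs.
#' @param mean,sd generating mean and SD (`sd > 0`).
#' @param icc within-pair correlation, in `[-1, 1]`.
#' @param scaleRange length-2 numeric, the admissible score range.
#' @param seed integer seed.
#' @return integer matrix `nPairs` x 2.
#' @export
genTraitPairs <- function(nPairs, mean, sd, icc, scaleRange = c(0, 192),
                          seed = 1L) {
  if (sd <= 0) stop("sd must be > 0")
  if (abs(icc) > 1) stop("icc must be in [-1, 1]")
  if (length(scaleRange) != 2L || scaleRange[1] >= scaleRange[2])
    stop("invalid scaleRange")
  set.seed(seed)
  u <- rnorm(nPairs)
  v <- rnorm(nPairs)
  x1 <- mean + sd * u
  x2 <- mean + sd * (icc * u + sqrt(1 - icc^2) * v)
  out <- cbind(x1, x2)
  out <- pmin(pmax(round(out), scaleRange[1]), scaleRange[2])
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Draw within-pair correlated percent-methylation values
#'
#' Zero-inflated, pair-correlated lognormal percent methylation: log-scale
#' bivariate normal whose correlation is chosen so the cross-twin
#' correlation of the back-transformed values is approximately `pairCorr`;
#' values are clipped to \[0, 100\], rounded to 2 decimals (pyrosequencing
#' reporting precision), and independently floored to exactly 0 with
#' probability `zeroMass` (assay detection floor). The marginal distribution
#' is right-skewed for any `logSd > 0`.
#'
#' @param nPairs number of pairs.
#' @param logMean,logSd log-scale location and scale (`logSd > 0`).
#' @param zeroMass zero-inflation probability, in `[0, 1)`.
#' @param pairCorr target within-pair correlation, in `[0, 1)`.
#' @param seed integer seed.
#' @return numeric matrix `nPairs` x 2 of percent methylation.
#' @export
genMethylationPairs <- function(nPairs, logMean, logSd, zeroMass = 0.05,
                                pairCorr = 0.4, seed = 1L) {
  if (logSd <= 0) stop("logSd must be > 0")
  if (zeroMass < 0 || zeroMass >= 1) stop("zeroMass must be in [0, 1)")
  if (pairCorr < 0 || pairCorr >= 1) stop("pairCorr must be in [0, 1)")
  set.seed(seed)
  # log-scale correlation giving lognormal-scale correlation ~ pairCorr
  rhoLog <- log(1 + pairCorr * (exp(logSd^2) - 1)) / logSd^2
  u <- rnorm(nPairs)
  v <- rnorm(nPairs)
  z1 <- u
  z2 <- rhoLog * u + sqrt(1 - rhoLog^2) * v
  m <- exp(logMean + logSd * cbind(z1, z2))
  m <- pmin(m, 100)
  zeros <- matrix(runif(2 * nPairs) < zeroMass, nPairs, 2L)
  m[zeros] <- 0
  round(m, 2L)
}

#' Plant a methylation-trait discordance effect
#'
#' Within each epigenetic-view pair, makes the higher-methylation twin (at
#' CpG `cpg`) also the higher-trait twin (`direction = "greater"`) or the
#' lower-trait twin (`direction = "less"`) on `scale` with probability
#' `0.5 + delta`, by conditionally swapping the two trait values within the
#' pair. Swapping never changes the within-pair multiset of scores, so
#' marginal trait distributions are untouched. Pairs tied on methylation or
#' on the trait are left as drawn.
#'
#' A `direction = "less"` plant raises the probability of the
#' higher-methylation / lower-trait configuration and is therefore the
#' signal the `"greater"` battery alternative tests for (and vice versa);
#' see [runEpigeneticBattery()].
#'
#' @param cohort a [TwinCohort-class].
#' @param cpg CpG index, 1..5.
#' @param scale scale name.
#' @param delta orientation probability shift, in `[0, 0.5]`.
#' @param direction `"greater"` or `"less"`: the trait rank, relative to the
#'   co-twin, the higher-methylation twin tends toward.
#' @param seed integer seed.
#' @return the modified `TwinCohort`.
#' @export
plantDiscordanceEffect <- function(cohort, cpg, scale, delta, direction,
                                   seed = 1L) {
  if (delta < 0 || delta > 0.5) stop("delta must be in [0, 0.5]")
  direction <- match.arg(direction, c("greater", "less"))
  col <- resolveScales(scale)
  set.seed(seed)
  epi <- epigeneticView(cohort)
  epiPairs <- unique(pairIds(epi))
  cd <- SummarizedExperiment::colData(cohort)
  meth <- methylation(cohort)
  idx <- pairIndex(cohort)
  for (pid in epiPairs) {
    i <- idx[, pid]
    m <- meth[cpg, i]
    tr <- cd[[col]][i]
    if (anyNA(m) || anyNA(tr) || m[1] == m[2] || tr[1] == tr[2]) {
      runif(1)  # keep the stream aligned across configurations
      next
    }
    wantConcordant <- runif(1) < 0.5 + delta
    hi <- which.max(m)
    isConcordant <- tr[hi] == max(tr)
    target <- if (direction == "greater") wantConcordant else !wantConcordant
    if (isConcordant != target) cd[[col]][i] <- rev(tr)
  }
  SummarizedExperiment::colData(cohort) <- cd
  cohort
}

#' Generate a synthetic twin cohort
#'
#' Assembles a full [TwinCohort-class] from a [simulationConfig()]:
#' pair-level zygosity, shared age and (for MZ) shared sex; Hardy-Weinberg
#' genotypes drawn once per MZ pair and independently per DZ twin;
#' within-pair correlated trait scores per scale (MZ at `iccMz`, DZ at
#' `iccMz / 2`); zero-inflated lognormal percent methylation for the first
#' `nEpiPairs` MZ pairs; then the optional genotype group shift and planted
#' discordance effect. Deterministic under a fixed seed: each sub-generator
#' (genotypes, each scale, each CpG, ...) draws from its own stream derived
#' from `config@seed`, so enabling one knob does not perturb the others'
#' draws.
#'
#' @param config a `SimulationConfig`.
#' @return `list(cohort = TwinCohort, truth = list)`; `truth` records every
#'   non-default generative choice (planted parameters, epigenetic pair ids,
#'   allele frequency, seeds) for parameter-recovery tests.
#' @examples
#' gc <- genCohort(simulationConfig(nPairsTotal = 10, nEpiPairs = 4, seed = 7))
#' gc$cohort
#' @export
genCohort <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  seed <- config@seed
  nP <- config@nPairsTotal
  nMz <- as.integer(round(nP * config@fractionMz))
  nDz <- nP - nMz
  zygPair <- c(rep("MZ", nMz), rep("DZ", nDz))
  pairId <- sprintf("P%04d", seq_len(nP))

  # ages: shared within pair, 18-60, resampled-truncated normal
  set.seed(.streamSeed(seed, "age"))
  agePair <- integer(nP)
  for (i in seq_len(nP)) {
    repeat {
      a <- round(rnorm(1, 24.66, 7.72))
      if (a >= 18 && a <= 60) break
    }
    agePair[i] <- a
  }

  set.seed(.streamSeed(seed, "sex"))
  sexPair <- ifelse(runif(nP) < 0.744, "F", "M")
  sexTwin2 <- ifelse(zygPair == "MZ", sexPair,
                     ifelse(runif(nP) < 0.744, "F", "M"))

  # genotypes: one HWE draw per MZ pair, independent draws per DZ twin
  gMz <- genGenotypesHwe(nMz, config@pMet, .streamSeed(seed, "genotype_mz"))
  gDz <- genGenotypesHwe(2L * nDz, config@pMet,
                         .streamSeed(seed, "genotype_dz"))
  geno1 <- c(gMz, if (nDz) gDz[seq_len(nDz)])
  geno2 <- c(gMz, if (nDz) gDz[nDz + seq_len(nDz)])

  cat35 <- neoScales()
  traits1 <- traits2 <- matrix(NA_integer_, nP, 35L,
                               dimnames = list(NULL, cat35$column))
  mzIdx <- which(zygPair == "MZ")
  dzIdx <- which(zygPair == "DZ")
  for (j in seq_len(35L)) {
    col <- cat35$column[j]
    rng <- c(cat35$min[j], cat35$max[j])
    sMz <- genTraitPairs(nMz, config@traitMeans[col], config@traitSds[col],
                         config@iccMz[col], rng,
                         .streamSeed(seed, paste0("trait_mz_", col)))
    traits1[mzIdx, j] <- sMz[, 1]
    traits2[mzIdx, j] <- sMz[, 2]
    if (nDz) {
      sDz <- genTraitPairs(nDz, config@traitMeans[col], config@traitSds[col],
                           config@iccMz[col] / 2, rng,
                           .streamSeed(seed, paste0("trait_dz_", col)))
      traits1[dzIdx, j] <- sDz[, 1]
      traits2[dzIdx, j] <- sDz[, 2]
    }
  }

  # interleave pair members: index twin (suffix a) first
  twins <- data.frame(
    twin_id = as.vector(rbind(paste0(pairId, "a"), paste0(pairId, "b"))),
    pair_id = rep(pairId, each = 2L),
    zygosity = rep(zygPair, each = 2L),
    sex = as.vector(rbind(sexPair, sexTwin2)),
    age = rep(agePair, each = 2L),
    genotype = as.vector(rbind(geno1, geno2)),
    stringsAsFactors = FALSE)
  traitTwin <- matrix(NA_integer_, 2L * nP, 35L,
                      dimnames = list(NULL, cat35$column))
  traitTwin[seq(1L, 2L * nP, by = 2L), ] <- traits1
  traitTwin[seq(2L, 2L * nP, by = 2L), ] <- traits2
  twins <- cbind(twins, as.data.frame(traitTwin))

  # genotype group shift (SNP-battery power plumbing)
  if (!is.null(config@groupShift)) {
    col <- resolveScales(config@groupShift$scale)
    j <- match(col, cat35$column)
    shift <- config@groupShift$deltaInSd * config@traitSds[col]
    met <- !is.na(twins$genotype) & twins$genotype == "Met/Met"
    twins[[col]][met] <- as.integer(pmin(pmax(
      round(twins[[col]][met] + shift), cat35$min[j]), cat35$max[j]))
  }

  # methylation for the first nEpiPairs MZ pairs
  meth <- matrix(NA_real_, 5L, 2L * nP)
  epiPairs <- pairId[mzIdx[seq_len(config@nEpiPairs)]]
  epiCols1 <- 2L * mzIdx[seq_len(config@nEpiPairs)] - 1L
  if (config@nEpiPairs > 0L) {
    for (k in 1:5) {
      mk <- genMethylationPairs(config@nEpiPairs, config@methLogMean[k],
                                config@methLogSd[k], config@methZeroMass[k],
                                config@methPairCorr,
                                .streamSeed(seed, paste0("meth_cpg", k)))
      meth[k, epiCols1] <- mk[, 1]
      meth[k, epiCols1 + 1L] <- mk[, 2]
    }
  }

  cohort <- TwinCohort(twins, meth)
  if (!is.null(config@plantedEffect)) {
    pe <- config@plantedEffect
    cohort <- plantDiscordanceEffect(cohort, pe$cpg, pe$scale, pe$delta,
                                     pe$direction,
                                     seed = .streamSeed(seed, "plant"))
  }
  truth <- list(seed = seed, pMet = config@pMet, epiPairs = epiPairs,
                plantedEffect = config@plantedEffect,
                groupShift = config@groupShift,
                iccMz = config@iccMz, methPairCorr = config@methPairCorr)
  list(cohort = cohort, truth = truth)
}
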