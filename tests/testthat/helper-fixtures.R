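# Hand-made MZ cohort fixtures for the discordance and IO tests.
#
# fixtureCohort(n): n MZ pairs, all twins genotyped Met/Val, facet scores 16
# and domain scores 100 unless overridden; methylation defaults to a
# tie-free per-twin constant across the 5 CpG sites.
#   meth   : 5 x 2n matrix, or a length-2n vector recycled to all CpGs
#   traits : named list, scale name -> length-2n integer vector
fixtureCohort <- function(n, meth = NULL, traits = list(),
                          genotype = "Met/Val") {
  cat35 <- neoScales()
  df <- data.frame(
    twin_id = paste0("T", seq_len(2L * n)),
    pair_id = rep(sprintf("P%02d", seq_len(n)), each = 2L),
    zygosity = "MZ", sex = "F", age = 30L,
    genotype = genotype, stringsAsFactors = FALSE)
  tm <- matrix(rep(ifelse(cat35$type == "domain", 100L, 16L),
                   each = 2L * n),
               nrow = 2L * n, dimnames = list(NULL, cat35$column))
  for (nm in names(traits)) tm[, resolveScales(nm)] <- traits[[nm]]
  df <- cbind(df, as.data.frame(tm))
  if (is.null(meth)) meth <- matrix(seq_len(2L * n), 5L, 2L * n,
                                    byrow = TRUE)
  if (is.null(dim(meth))) meth <- matrix(rep(meth, each = 5L), 5L)
  TwinCohort(df, meth)
}

# A small all-MZ null cohort whose epigenetic view covers every pair.
nullEpiCohort <- function(nPairs, seed, plantedEffect = NULL) {
  genCohort(simulationConfig(nPairsTotal = as.integer(nPairs),
                             fractionMz = 1, nEpiPairs = as.integer(nPairs),
                             plantedEffect = plantedEffect,
                             seed = as.integer(seed)))$cohort
}
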