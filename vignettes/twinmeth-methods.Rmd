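---
title: "Methods: candidate-gene association and twin methylation discordance"
author: "twinmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene association and twin methylation discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmeth)
```

## The scientific setting

`twinmeth` operationalises a two-arm analysis of personality genetics in a
twin cohort. The phenotype battery is the NEO-PI-R: five Five-Factor-Model
domains, each with six facets, 35 scales in all (`neoScales()`). The
candidate gene is *COMT*, whose Val158Met (rs4680) polymorphism modulates
dopamine clearance in the prefrontal cortex, and whose brain-predominant
membrane-bound isoform (*MB-COMT*) carries a promoter region assayed by
bisulfite pyrosequencing at five CpG sites, reported as percent methylation
per site.

* **SNP arm.** Every twin is an observation. Under a dominant coding, Val
  carriers (Val/Val, Met/Val) form the Val+ group and Met/Met homozygotes
  the Met+ group; each of the 35 scales is compared across groups with an
  assumption-gated two-sample test.
* **Epigenetic arm.** Monozygotic (MZ) twin pairs are the observations.
  Because MZ co-twins are genetically identical, a within-pair difference
  in promoter methylation isolates non-genetic variation; the analysis asks
  whether the higher-methylation twin of a pair tends to be the higher- or
  lower-scoring twin on each scale, via 2x2 contingency tables and
  Barnard's unconditional exact test.

A synthetic cohort generator (`genCohort()`) supplies data with the
statistical structure the two arms assume, so the whole pipeline is
testable end to end.

## The SNP battery

For each scale, with Met+ scores $x$ and Val+ scores $y$:

1. **Gates.** Shapiro–Wilk normality per group and a mean-centred Levene
   test for variance homogeneity, both at $\alpha = 0.05$. The tests and
   the level are arguments (`chooseTest()`); the defaults are the common
   desktop-statistics choices. Normality is assessed per group because the
   t-test assumption is per group.
2. **Routing.** Normality failing in either group sends the comparison to
   the Mann–Whitney U test; otherwise a variance-homogeneity failure sends
   it to Welch's t; otherwise the pooled-variance Student t is used.
3. **Effect sizes.** Cohen's $d = (\bar x - \bar y)/s_p$ with the exact
   noncentral-t confidence interval for the t routes; for the U route, the
   rank-biserial correlation $r = 2U/(n_1 n_2) - 1$, where $U$ counts Met+
   over Val+ dominances with half credit for ties, so $r > 0$ means Met+
   scores higher. Its CI uses the normal approximation on the U scale,
   $\mathrm{SE}(U) = \sqrt{n_1 n_2 (n_1+n_2+1)/12}$, mapped through the
   same transform and clipped to $[-1, 1]$. The published analysis this
   package reimplements does not state its CI construction, so exact
   agreement with published intervals is not claimed.
4. **Multiplicity.** Bonferroni with family size $m = 2$:
   $p_{\mathrm{bonf}} = \min(1, 2p)$. Every published adjusted p-value in
   the source analysis equals this transform of its raw p, so $m = 2$ is
   the default; the family size is an argument because the choice is a
   reporting convention, not a statistical necessity.

The Mann–Whitney p-value uses the tie- and continuity-corrected normal
approximation when both groups exceed 20 (always the case at the study's
group sizes of 129 and 301) and exact enumeration of the permutation
distribution for smaller groups, using the symmetric distance
$|U - n_1 n_2 / 2|$; enumeration is capped at $2\times 10^5$ group
assignments.

**Caveat: twin clustering.** The battery treats all 430 twins as
independent, as the group sizes and U statistics of the source analysis
imply. MZ co-twins share their genotype and correlate on traits, so a pair
usually sits entirely inside one genotype group and the independence
assumption is optimistic: with within-pair ICC near 0.5 the realised type I
error of the battery is roughly double the nominal 5% (the test suite
measures about 10–11% on default-ICC null cohorts). We replicate the
procedure and document the caveat rather than correcting it; the
calibration property test therefore checks the nominal level where the
assumption actually holds (ICC 0), and the vignette is the warning label
for real data.

**Hardy–Weinberg check.** `hweChiSquare()` computes the standard
goodness-of-fit statistic with the allele frequency estimated from the
data, hence df = 1 for the p-value. Recomputing from the published genotype
counts (129/224/77 and 23/37/10) gives $\chi^2 = 1.41$ and $0.63$ — not
the published 0.85 and 5.06 (df = 2), which cannot be recovered from the
printed counts under the standard statistic. The package does not
reverse-engineer those values; a `labelDf2` flag reproduces the df = 2
labelling convention without touching the computation. Either way both
samples are compatible with equilibrium at $\alpha = 0.05$.

## The discordance battery

For each of the 5 CpG sites, 35 scales and two one-sided alternatives
(350 cells):

1. **Orientation.** Within each epigenetic-view pair, the twin with the
   higher percent methylation at the cell's CpG is labelled H, the co-twin
   L. A pair with identical values at that CpG (in practice two zeros) is
   excluded *for that CpG only*; missing data exclude per cell.
2. **Trait status and tie rules.** Let $p_1$ be the probability that a twin
   has higher methylation *and* a lower trait score than its sibling, and
   $p_2$ the probability of higher methylation and a higher score. The
   `"greater"` alternative tests $H_1: p_1 > p_2$; trait columns are
   Higher/NotHigher and trait ties count as NotHigher for both twins. The
   `"less"` alternative tests $H_1: p_1 < p_2$ with columns Lower/NotLower
   and ties as NotLower. Trait ties never exclude a pair.
3. **Table construction.** The success column is fixed to "lower trait"
   (NotHigher under `"greater"`, Lower under `"less"`), so the Barnard
   alternative label maps directly onto the $p_1$ vs $p_2$ hypothesis.
   Two designs are available:
   * `pairContribution = "index_twin"` (default): one observation per
     pair. Rows split the pairs by whether the *first* twin in cohort
     order is the higher-methylation twin, and the column records that
     twin's trait status — the four-way pair classification
     (higher/lower methylation x higher/lower trait for the first twin)
     of the source analysis. Under the null, given the row sizes, the row
     successes are independent Bernoulli(1/2), so the unconditional test
     keeps its size guarantee; with twin labels exchangeable, the row-1
     success proportion estimates $p_1/(p_1+p_2)$ and row 2 its
     complement, making the 2x2 test exactly a test of $p_1$ vs $p_2$.
   * `pairContribution = "both_twins"`: each pair contributes one twin to
     each row (fixed rows of size $n_{\mathrm{pairs}}$, mirrored counts:
     on tie-free data $x_2 = n_1 - x_1$). The rows are then perfectly
     dependent, the variance of $\hat p_1 - \hat p_2$ is twice what the
     two-binomial null assumes, and the test is anti-conservative (the
     test suite measures roughly 9–10% rejection at nominal 5% with 35
     pairs). It is retained behind the switch for comparison, with this
     caveat as its documentation.
4. **Testing.** Each cell gets a one-sided Barnard p-value; no
   multiplicity correction is applied across the 350 cells by default,
   matching the source analysis (`bh = TRUE` appends a labelled
   Benjamini–Hochberg column without changing the defaults).

## Barnard's unconditional exact test

For a 2x2 table with fixed row sizes $n_1, n_2$ and success counts
$x_1, x_2$, the test orders tables by the pooled Wald (score) statistic

$$T = \frac{\hat p_1 - \hat p_2}
       {\sqrt{\hat p (1-\hat p)\,(1/n_1 + 1/n_2)}},
\qquad \hat p = \frac{x_1 + x_2}{n_1 + n_2},$$

with $T = 0$ by convention when $\hat p \in \{0, 1\}$ (a totally degenerate
table carries no directional evidence). The p-value is

$$p = \sup_{\pi \in (0,1)} \sum_{(k_1,k_2)\,:\,T(k_1,k_2) \succeq T_{\mathrm{obs}}}
      \binom{n_1}{k_1}\pi^{k_1}(1-\pi)^{n_1-k_1}
      \binom{n_2}{k_2}\pi^{k_2}(1-\pi)^{n_2-k_2},$$

where $\succeq$ is $\ge$ for `"greater"`, $\le$ for `"less"`, and
$|T| \ge |T_{\mathrm{obs}}|$ for `"two.sided"` (ordering by $|T|$, not
doubling). Ties in $T$ are included in the extreme region (a $10^{-9}$
tolerance absorbs floating-point noise between algebraically equal
statistics). The pooled-statistic ordering is the convention of the
standard scientific-computing implementation of this test, so results are
comparable across stacks; the ordering function is the one pluggable
numerical choice a reimplementation must fix.

**Numerics.** The supremum is located on a uniform grid of 1001 points over
$(10^{-6}, 1-10^{-6})$ — $p(\pi)$ is a single polynomial in $\pi$ once the
extreme region is fixed, with few local maxima at these sample sizes — and
then sharpened by golden-section search between the grid neighbours of the
best point. `barnardOracle()` recomputes the same definition the slow way
(explicit table enumeration, dense 100,001-point grid, no refinement) and
is the verification standard in the test suite: the fast path agrees with
it to $10^{-6}$ on random tables, and exhaustive enumeration for
$n_1 = n_2 \le 10$ confirms the finite-sample size guarantee
(rejection probability $\le \alpha$ at every nuisance value). Doubling the
grid changes p-values by less than $10^{-4}$.

Fisher's conditional test (`fisherP()`) is the comparator: on tables with
evidence in the tested direction the unconditional p never exceeded the
conditional one in our exhaustive $n_1 = n_2 = 8$ sweep, which is the power
rationale for preferring Barnard's test at these sample sizes.

## The synthetic cohort generator

Defaults reproduce the study conditions of the source cohort: 215 pairs
(430 twins), 75.8% MZ, an epigenetic subsample of 35 MZ pairs, Met allele
frequency $482/860 \approx 0.56$, ages 18–60 (truncated normal, mean 24.7,
SD 7.7, shared within pair), 74.4% female.

* **Genotypes** are Hardy–Weinberg draws — once per MZ pair (co-twins are
  genetically identical) and independently per DZ twin. DZ pairs exist for
  cohort realism only; shared parentage is not modelled and the epigenetic
  arm never uses them.
* **Traits** are bivariate normal within pair with common mean/SD and
  correlation `iccMz` (default 0.5 per scale; DZ pairs use half of it),
  rounded to integers and clipped to the scale range. Domain means/SDs
  default to the published descriptive moments; facet defaults take
  mean/6 and SD/$\sqrt 6$ — a deliberate simplification (item sums would
  correlate facets; here scales are independent).
* **Methylation** is zero-inflated pair-correlated lognormal, clipped to
  [0, 100] and rounded to 2 decimals: the published per-CpG moments show
  strictly positive skew with zero minima, and the lognormal is the
  simplest right-skewed family matching a mean/SD pair. Log-scale
  parameters are moment-matched per CpG; the log-scale correlation is
  chosen so the back-transformed cross-twin correlation is approximately
  `methPairCorr`. The default pair correlation 0.4 and zero mass 0.05 are
  package choices — the source reports neither — and are flagged as such
  here rather than tuned.
* **Planted effects.** `plantDiscordanceEffect()` conditionally swaps the
  two trait values within a pair so the higher-methylation twin ends up on
  the `direction` side of its co-twin with probability $0.5 + \delta$;
  swapping preserves the within-pair multiset of scores, so marginals are
  untouched. A `direction = "less"` plant (higher methylation, lower
  trait) raises $p_1$ and is therefore detected under the `"greater"`
  battery alternative, and vice versa — the direction names the planted
  orientation, the alternative names the hypothesis. `groupShift` adds a
  crude mean shift to the Met/Met group on one scale for SNP-arm power
  studies.
* **Reproducibility.** One global seed; every sub-generator (each scale,
  each CpG, genotypes, ages, the planting pass) derives its own stream
  from a labelled hash of it, so switching one knob never perturbs the
  other draws, and identical configs give byte-identical cohort CSVs.

What the generator does *not* emulate: cross-scale correlations (real
domains and facets correlate strongly), genotype effects on traits other
than the optional crude shift, age/sex structure in traits or methylation,
assay batch effects, and any genotype–methylation dependence. Passing
calibration and recovery tests on these cohorts therefore demonstrates the
statistical machinery, not robustness to those real-data features.

## Worked example

```{r example}
cohort <- genCohort(simulationConfig(seed = 42L))$cohort
cohort

snp <- runSnpBattery(cohort)
head(snp[, c("scale", "test", "statistic", "p", "p_bonf", "effect")], 3)

cells <- runEpigeneticBattery(cohort)
head(summarizeSignificant(cells, alpha = 0.05)$table[,
  c("cpg", "scale", "alternative", "x1", "n1", "x2", "n2", "p_value")], 3)
```

## Problem sizes in the test suite

The suite verifies the Barnard implementation against its dense-grid
oracle on 200 random tables with $n_1, n_2 \le 12$ and enumerates the size
guarantee exhaustively for $n_1 = n_2 \le 10$; battery calibration uses 200
null 35-pair cohorts, discordance-effect recovery 500 planted cohorts, and
SNP-arm power 100 cohorts of 430 twins. These sizes were chosen to hold
Monte-Carlo error comfortably below the tested margins while keeping the
suite quick to run.

## Known limitations

* Twins enter the SNP battery as independent observations (see above); no
  mixed-model or cluster-robust variant is provided.
* The discordance battery dichotomises within-pair differences; a
  continuous within-pair regression would use more information but is a
  different estimand and is out of scope.
* Only the dominant genotype coding is implemented; additive and recessive
  codings, covariate adjustment, and genotype x methylation interaction
  are not.
* The rank-biserial CI is a normal approximation on U; bootstrap or exact
  alternatives are not provided.
* Percent methylation from buccal-swab pyrosequencing is an imperfect
  proxy for brain promoter methylation; nothing in the statistics corrects
  for tissue differences.
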