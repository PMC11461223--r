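Package: twinmeth
Title: Twin-Based Promoter Methylation Discordance and Candidate-Gene
    Association Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for candidate-gene and epigenetic twin studies
    of personality. Implements a dominant-model COMT Val158Met (rs4680)
    association battery over NEO-PI-R domains and facets with
    assumption-gated test selection (Student t, Welch t, Mann-Whitney U),
    Cohen's d and rank-biserial effect sizes with confidence intervals,
    Bonferroni adjustment, and a Hardy-Weinberg equilibrium check; and a
    monozygotic-twin within-pair discordance analysis linking MB-COMT
    promoter CpG percent-methylation to trait expression through 2x2
    contingency tables tested with a from-scratch Barnard unconditional
    exact test. A synthetic twin-cohort generator with planted effects makes
    every stage testable without access to the original cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
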