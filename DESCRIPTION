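Package: mirtraj
Title: Trajectory-Class Differential Expression and miRNA Regulator
    Nomination for Differentiation RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for paired mRNA/miRNA count data from
    a two-genotype by two-stage differentiation design. Provides TMM
    library normalization and log-CPM computation, a fixed-dispersion
    negative-binomial exact test for differential expression, four-class
    expression-trajectory classification (joint response to
    differentiation and genotype), one-sided Fisher exact gene-set
    enrichment, and nomination of candidate miRNA regulators from the
    anti-correlation between a miRNA and its annotated targets (per-pair
    Pearson correlation, one-sample one-sided Wilcoxon shift test).
    Includes a seeded negative-binomial simulator with planted trajectory
    classes and miRNA-target repression coupling for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
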